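# Packaged benchmark fixtures: a published 11-strain human-associated
# mock community (equal cell numbers, copy numbers from the rrn database
# taking the larger value when several are reported), the per-method
# observed read-proportion summaries (means and SDs over eight
# replicates), and the per-method x per-sample mean DNA yields.

mockbench_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mockbench")
  if (!nzchar(path)) stop("packaged fixture not found: ", file)
  path
}

#' The packaged 11-strain benchmark community
#'
#' Eleven human-associated type strains mixed at equal cell numbers, with
#' 16S rRNA gene copy numbers (7, 6, 4, 7, 8, 4, 5, 4, 2, 2, 3). This is
#' the ground-truth community used throughout the package's examples and
#' acceptance checks.
#'
#' @return a [mock_community()] with 11 taxa.
#' @export
mock11_community <- function() {
  load_community(mockbench_extdata("mock11_community.tsv"))
}

#' Published observed-proportion summaries for the benchmark community
#'
#' Mean and standard deviation (percent, eight replicates) of the
#' observed read proportions of each taxon under six DNA extraction
#' methods. These summaries are the input for [table4_fixture()], which
#' reconstructs plausible per-replicate count tables from them.
#'
#' @return data frame with columns `taxon`, `method`, `mean_pct`,
#'   `sd_pct`.
#' @export
mock11_observed <- function() {
  read.delim(mockbench_extdata("mock11_observed_proportions.tsv"),
             stringsAsFactors = FALSE)
}

#' Published mean DNA yields for the benchmark experiment
#'
#' Mean DNA concentrations (ug/ml, eight replicates) per extraction
#' method for each of the eleven strains and the pooled mock community.
#' Suitable input for [yield_summary()].
#'
#' @return data frame with columns `sample`, `method`, `concentration`.
#' @export
mock11_yield_means <- function() {
  read.delim(mockbench_extdata("mock11_yield_means.tsv"),
             stringsAsFactors = FALSE)
}
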