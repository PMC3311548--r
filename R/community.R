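# Mock community definitions and expected read proportions.

#' Define a mock community
#'
#' A mock community is an ordered set of taxa, each with a 16S rRNA gene
#' copy number (genomic copies per cell) and a relative cell abundance.
#' The row order fixes the vector indexing used by every downstream
#' function; all proportion vectors carry the taxa as names and are
#' checked against each other.
#'
#' @param name character vector of unique, non-empty taxon labels.
#' @param copy_number positive integers, 16S rRNA gene copies per genome.
#'   Where a strain has several reported values the convention is to take
#'   the larger.
#' @param cell_fraction non-negative relative cell abundances
#'   (unnormalized; default 1 = equal cell numbers). At least one must be
#'   positive.
#' @return a `mock_community` data frame with columns `name`,
#'   `copy_number`, `cell_fraction`.
#' @examples
#' mock_community(c("A", "B", "C"), copy_number = c(1, 2, 2),
#'                cell_fraction = c(2, 1, 1))
#' @export
mock_community <- function(name, copy_number, cell_fraction = 1) {
  name <- as.character(name)
  if (length(name) == 0) stop("community must contain at least one taxon")
  if (any(!nzchar(name)) || anyNA(name)) {
    stop("taxon names must be non-empty")
  }
  dup <- unique(name[duplicated(name)])
  if (length(dup)) {
    stop("duplicate taxon name(s): ", paste(dup, collapse = ", "))
  }
  if (length(copy_number) != length(name)) {
    stop("copy_number must have one value per taxon")
  }
  if (any(!is_whole(copy_number)) || any(copy_number < 1)) {
    bad <- name[!is_whole(copy_number) | copy_number < 1]
    stop("copy_number must be a positive integer; offending taxa: ",
         paste(bad, collapse = ", "))
  }
  cell_fraction <- rep_len(as.numeric(cell_fraction), length(name))
  if (anyNA(cell_fraction) || any(cell_fraction < 0)) {
    bad <- name[is.na(cell_fraction) | cell_fraction < 0]
    stop("cell_fraction must be non-negative; offending taxa: ",
         paste(bad, collapse = ", "))
  }
  out <- data.frame(name = name,
                    copy_number = as.integer(round(copy_number)),
                    cell_fraction = cell_fraction,
                    stringsAsFactors = FALSE)
  class(out) <- c("mock_community", "data.frame")
  out
}

#' @export
print.mock_community <- function(x, ...) {
  cat("Mock community with", nrow(x), "taxa\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Expected read proportions of a mock community
#'
#' Under unbiased extraction and amplification the expected share of 16S
#' reads of taxon i is proportional to cell_fraction * copy_number:
#' \deqn{\pi_i = c_i g_i / \sum_j c_j g_j.}
#'
#' @param community a [mock_community()].
#' @return named numeric vector of proportions summing to 1, in community
#'   order.
#' @examples
#' cm <- mock_community(c("A", "B"), copy_number = c(2, 1))
#' expected_proportions(cm)  # 2/3, 1/3
#' @export
expected_proportions <- function(community) {
  stopifnot(inherits(community, "mock_community"))
  w <- community$cell_fraction * community$copy_number
  if (all(w == 0)) {
    stop("degenerate community: all cell fractions are zero")
  }
  p <- w / sum(w)
  names(p) <- community$name
  validate_proportions(p, "expected proportions")
  p
}

#' Read a mock community from TSV or JSON
#'
#' The TSV layout is a header `name	copy_number	cell_fraction` with one
#' row per taxon; `cell_fraction` may be omitted (defaults to 1, i.e.
#' equal cell numbers). The JSON layout is an object with a `taxa` array
#' of `{name, copy_number, cell_fraction}` records. Taxa keep file order.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"` or `"json"`.
#' @return a [mock_community()].
#' @seealso [write_community()], [mock11_community()] for the packaged
#'   11-strain benchmark community.
#' @export
load_community <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    df <- as.data.frame(obj$taxa)
  } else {
    df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  }
  if (!all(c("name", "copy_number") %in% names(df))) {
    stop("community file must have columns 'name' and 'copy_number'")
  }
  if (is.null(df$cell_fraction)) df$cell_fraction <- 1
  mock_community(df$name, df$copy_number, df$cell_fraction)
}

#' Write a mock community to TSV or JSON
#'
#' @param community a [mock_community()].
#' @param path output file path.
#' @param format `"auto"`, `"tsv"` or `"json"` (see [load_community()]).
#' @return `path`, invisibly.
#' @export
write_community <- function(community, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(community, "mock_community"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    jsonlite::write_json(list(taxa = as.data.frame(unclass(community))),
                         path, auto_unbox = FALSE, digits = NA)
  } else {
    write.table(as.data.frame(unclass(community)), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
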