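# Representation and reproducibility scoring, and the statistical tests
# used to compare extraction methods.
#
# Distances are computed on fractions (0-1), not percent; using percent
# would only rescale every distance by 100.

#' Euclidean distance between two proportion vectors
#'
#' @param p,q numeric vectors over the same taxa in the same order (names,
#'   when present on both, are checked).
#' @return `sqrt(sum((p - q)^2))`.
#' @export
euclidean_distance <- function(p, q) {
  check_same_taxa(p, q)
  sqrt(sum((p - q)^2))
}

#' Representation scores (distance to expectation)
#'
#' One Euclidean distance per replicate between its observed proportions
#' and the expected proportions. Accurate methods have distances close to
#' zero.
#'
#' @param table a [count_table()].
#' @param expected expected proportions ([expected_proportions()]).
#' @return named numeric vector, one distance per replicate.
#' @export
representation_scores <- function(table, expected) {
  stopifnot(inherits(table, "count_table"))
  validate_proportions(expected, "expected proportions")
  obs <- observed_proportions(table)
  if (nrow(obs) != length(expected)) {
    stop("count table and expected proportions have different lengths")
  }
  apply(obs, 2, function(col) sqrt(sum((col - expected)^2)))
}

#' Reproducibility scores (distance to the pooled baseline)
#'
#' One Euclidean distance per replicate between its observed proportions
#' and the grand (pooled) proportions of its table. Reproducible methods
#' have small deviations from this baseline.
#'
#' @param table a [count_table()] with at least two replicates.
#' @return named numeric vector, one distance per replicate.
#' @export
reproducibility_scores <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$counts) < 2) {
    stop("reproducibility requires at least two replicates")
  }
  baseline <- grand_proportions(table)
  obs <- observed_proportions(table)
  apply(obs, 2, function(col) sqrt(sum((col - baseline)^2)))
}

#' Wilcoxon rank sum test (two-sided)
#'
#' Thin, contract-checked interface over [stats::wilcox.test()]. In
#' `"auto"` mode the exact distribution is used when both samples are
#' untied and the pooled size is at most 20; otherwise the normal
#' approximation with tie and continuity corrections is used. The choice
#' actually applied is reported.
#'
#' @param x,y numeric samples (each non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal"`. `"exact"` falls back to
#'   `"normal"` (with a message in `mode_used`) when ties or size make the
#'   exact distribution unavailable.
#' @return list with `statistic` (Mann-Whitney U for `x`), `rank_sum`
#'   (rank sum of `x`), `p_value`, `mode_used`.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  feasible <- !ties && (length(x) + length(y)) <= 20
  use_exact <- switch(mode,
                      auto = feasible,
                      exact = feasible,  # auto-fallback on ties / large n
                      normal = FALSE)
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE,
                alternative = "two.sided")
  )
  u <- unname(wt$statistic)
  list(statistic = u,
       rank_sum = u + length(x) * (length(x) + 1) / 2,
       p_value = wt$p.value,
       mode_used = if (use_exact) "exact" else "normal")
}

#' Fligner-Killeen test of homogeneity of variances
#'
#' Rank-based variance comparison (median-centered absolute values,
#' normal-score ranks, chi-squared statistic with k - 1 df), via
#' [stats::fligner.test()]. The degenerate case where every observation
#' equals its group median (zero spread everywhere) returns statistic 0
#' and p-value 1.
#'
#' @param groups list of numeric samples (>= 2 groups, each n >= 2).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
fligner_killeen <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("groups must be a list of at least two samples")
  }
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  centered <- unlist(lapply(groups, function(g) abs(g - median(g))))
  if (all(centered == 0)) {
    return(list(statistic = 0, df = length(groups) - 1, p_value = 1))
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ft <- fligner.test(values, g)
  list(statistic = unname(ft$statistic),
       df = unname(ft$parameter),
       p_value = ft$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of (average) ranks; the p-value uses the
#' t-distribution approximation.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return list with `rho`, `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("correlation undefined for a constant vector")
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, m * p)` with `m` the declared family size (default: the number
#' of p-values supplied).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param m family size.
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, m * p_values)
}

# Distances split by a metadata field into its two blocks; exact Wilcoxon
# when feasible. Returns NULL when the field is missing or not two-level.
block_comparison <- function(distances, meta, field) {
  if (is.null(meta) || all(is.na(meta[[field]]))) return(NULL)
  lev <- unique(meta[[field]])
  if (length(lev) != 2) return(NULL)
  a <- distances[meta[[field]] == lev[1]]
  b <- distances[meta[[field]] == lev[2]]
  w <- wilcoxon_rank_sum(a, b)
  list(field = field, levels = lev, statistic = w$statistic,
       p_value = w$p_value, mode_used = w$mode_used)
}

#' Compare extraction methods end to end
#'
#' Runs the full evaluation over one count table per method:
#' representation scores (distance to expectation), reproducibility
#' scores (distance to each method's pooled baseline), all-pairs Wilcoxon
#' rank sum tests on representation distances, all-pairs Fligner-Killeen
#' tests on reproducibility deviations (both Bonferroni-adjusted over the
#' all-pairs family), within-method experimenter/day Wilcoxon comparisons
#' of representation distances (when metadata is available), and Spearman
#' correlation of DNA yield against representation distance within and
#' across methods (when yields are supplied).
#'
#' @param tables named list of [count_table()]s, one per method (>= 2);
#'   names are the method labels and must be unique.
#' @param expected expected proportions shared by all methods.
#' @param yields optional [yield_table()]; rows whose `sample` equals
#'   `yield_sample` are matched to replicates by method and column order.
#' @param alpha significance level recorded in the report.
#' @param yield_sample which yield sample to correlate (default `"mock"`).
#' @return an `evaluation_report` list; see Details in the vignette.
#' @export
compare_methods <- function(tables, expected, yields = NULL, alpha = 0.05,
                            yield_sample = "mock") {
  if (!is.list(tables) || length(tables) < 2) {
    stop("need count tables for at least two methods")
  }
  methods <- names(tables)
  if (is.null(methods) || any(!nzchar(methods)) || anyDuplicated(methods)) {
    stop("tables must be uniquely named by method label")
  }
  methods <- sort(methods)  # canonical order: output invariant to input order
  tables <- tables[methods]

  rep_scores <- lapply(tables, representation_scores, expected = expected)
  repro_scores <- lapply(tables, reproducibility_scores)

  pairs <- combn(methods, 2, simplify = FALSE)
  m_family <- length(pairs)
  pair_row <- function(pair, scores, test) {
    a <- scores[[pair[1]]]; b <- scores[[pair[2]]]
    if (test == "wilcoxon") {
      r <- wilcoxon_rank_sum(a, b)
      data.frame(method_a = pair[1], method_b = pair[2],
                 statistic = r$statistic, raw_p = r$p_value,
                 stringsAsFactors = FALSE)
    } else {
      r <- fligner_killeen(list(a, b))
      data.frame(method_a = pair[1], method_b = pair[2],
                 statistic = r$statistic, raw_p = r$p_value,
                 stringsAsFactors = FALSE)
    }
  }
  rep_tests <- do.call(rbind, lapply(pairs, pair_row, scores = rep_scores,
                                     test = "wilcoxon"))
  rep_tests$adjusted_p <- bonferroni_adjust(rep_tests$raw_p, m_family)
  repro_tests <- do.call(rbind, lapply(pairs, pair_row, scores = repro_scores,
                                       test = "fligner"))
  repro_tests$adjusted_p <- bonferroni_adjust(repro_tests$raw_p, m_family)

  block_tests <- lapply(methods, function(m) {
    meta <- tables[[m]]$meta
    list(method = m,
         experimenter = block_comparison(rep_scores[[m]], meta, "experimenter"),
         day = block_comparison(rep_scores[[m]], meta, "day"))
  })
  names(block_tests) <- methods

  correlation <- NULL
  if (!is.null(yields)) {
    ys <- as.data.frame(yields)
    ys <- ys[ys$sample == yield_sample, , drop = FALSE]
    per_method <- lapply(methods, function(m) {
      d <- rep_scores[[m]]
      y <- ys$concentration[ys$method == m]
      if (length(y) != length(d)) {
        stop("yield table has ", length(y), " '", yield_sample,
             "' records for method ", m, " but the count table has ",
             length(d), " replicates")
      }
      c(spearman_correlation(y, d), list(method = m, n = length(d)))
    })
    names(per_method) <- methods
    all_y <- unlist(lapply(methods, function(m) ys$concentration[ys$method == m]))
    all_d <- unlist(rep_scores[methods])
    correlation <- list(within = per_method,
                        across = spearman_correlation(all_y, all_d))
  }

  structure(list(methods = methods,
                 alpha = alpha,
                 representation = rep_scores,
                 reproducibility = repro_scores,
                 representation_tests = rep_tests,
                 reproducibility_tests = repro_tests,
                 block_tests = block_tests,
                 correlation = correlation,
                 family_size = m_family),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation of", length(x$methods), "methods:",
      paste(x$methods, collapse = ", "), "\n")
  cat("Mean representation distance per method:\n")
  print(round(vapply(x$representation, mean, numeric(1)), 4))
  sig <- x$representation_tests$adjusted_p < x$alpha
  cat(sum(sig), "of", nrow(x$representation_tests),
      "pairwise representation comparisons significant at adjusted alpha =",
      x$alpha, "\n")
  invisible(x)
}

#' Serialize / deserialize an evaluation report as JSON
#'
#' The round trip `write_evaluation_report()` then
#' [read_evaluation_report()] preserves every field.
#'
#' @param report an `evaluation_report` from [compare_methods()].
#' @param path file path.
#' @return `path` (writer) or the report (reader), invisibly for the writer.
#' @export
write_evaluation_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- unclass(report)
  # keep replicate ids: named vectors serialize as JSON objects, not arrays
  for (f in c("representation", "reproducibility")) {
    obj[[f]] <- lapply(obj[[f]], as.list)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_evaluation_report
#' @export
read_evaluation_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (f in c("representation", "reproducibility")) {
    obj[[f]] <- lapply(obj[[f]], function(v) unlist(v))
  }
  obj$representation_tests <- as.data.frame(obj$representation_tests)
  obj$reproducibility_tests <- as.data.frame(obj$reproducibility_tests)
  structure(obj, class = "evaluation_report")
}

#' Export per-method distance data for plotting
#'
#' Writes a long-format TSV (`method`, `replicate_id`, `metric`,
#' `distance`) with the representation and reproducibility distances of
#' an evaluation report, suitable for external boxplot rendering.
#'
#' @param report an `evaluation_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  rows <- list()
  for (metric in c("representation", "reproducibility")) {
    for (m in report$methods) {
      d <- report[[metric]][[m]]
      rows[[length(rows) + 1]] <- data.frame(
        method = m, replicate_id = names(d), metric = metric, distance = d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
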