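# DNA-yield analysis: split-plot ANOVA on log concentrations, per-sample
# Tukey HSD, compact letter displays and the headline summaries.

#' Build a DNA-yield table
#'
#' Long-format records of DNA concentration (ug/ml) per extraction
#' method, sample (a species or the pooled `"mock"` community),
#' replicate, experimenter and day. Experimenter and day are the blocking
#' labels of the 2 experimenters x 2 days x 2 replicates layout.
#'
#' @param records data frame with columns `method`, `sample`,
#'   `replicate`, `experimenter`, `day`, `concentration` (`experimenter`
#'   and `day` may be absent for summary-only uses).
#' @return a `yield_table` data frame.
#' @export
yield_table <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  need <- c("method", "sample", "replicate", "concentration")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("yield records lack column(s): ",
                         paste(miss, collapse = ", "))
  if (anyNA(records$concentration) || any(records$concentration < 0)) {
    bad <- which(is.na(records$concentration) | records$concentration < 0)[1]
    stop("concentration must be non-negative; offending record ", bad)
  }
  for (f in c("experimenter", "day")) {
    if (is.null(records[[f]])) records[[f]] <- NA_character_
  }
  records$method <- as.character(records$method)
  records$sample <- as.character(records$sample)
  attr(records, "log_transformed") <- isTRUE(attr(records, "log_transformed"))
  class(records) <- c("yield_table", "data.frame")
  records
}

#' Read / write a yield table as TSV
#'
#' Columns: `method`, `sample`, `replicate`, `experimenter`, `day`,
#' `concentration`.
#'
#' @param path file path.
#' @return a [yield_table()].
#' @export
read_yield_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  yield_table(read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_yield_table
#' @param table a [yield_table()].
#' @export
write_yield_table <- function(table, path) {
  stopifnot(inherits(table, "yield_table"))
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Log-transform yield concentrations
#'
#' Natural log, applied to accommodate normality and constant-variance
#' assumptions of the ANOVA. Zero concentrations are an error: substitute
#' a detection limit upstream if needed. The transformation is recorded
#' in the table's provenance attribute and applied at most once by
#' [splitplot_anova()] and [tukey_hsd_per_sample()].
#'
#' @param table a [yield_table()].
#' @return the transformed [yield_table()].
#' @export
log_transform_yields <- function(table) {
  stopifnot(inherits(table, "yield_table"))
  if (attr(table, "log_transformed")) {
    stop("yield table is already log-transformed")
  }
  zero <- which(table$concentration <= 0)
  if (length(zero)) {
    stop("non-positive concentration in record(s) ",
         paste(zero, collapse = ", "),
         "; substitute a detection limit before log-transforming")
  }
  table$concentration <- log(table$concentration)
  attr(table, "log_transformed") <- TRUE
  table
}

# Single blocking label: experimenter and day are confounded in the
# 2 x 2 layout (each experimenter works on both days but the design
# cannot separate them), so they collapse into one block factor.
block_label <- function(table) {
  e <- table$experimenter
  d <- table$day
  if (all(is.na(e)) && all(is.na(d))) {
    stop("split-plot ANOVA needs experimenter and/or day block labels")
  }
  if (all(is.na(d))) return(as.character(e))
  if (all(is.na(e))) return(as.character(d))
  paste(e, d, sep = "/")
}

#' Balanced split-plot ANOVA of log DNA yields
#'
#' The design has extraction method as the whole-plot factor, sample
#' (species) as the split-plot factor, and experimenter(/day) as a random
#' block. Sums of squares use the balanced closed forms; the method F
#' ratio is tested against the whole-plot error (block x method), while
#' sample and method x sample are tested against the residual.
#' Concentrations are log-transformed first unless the table already is.
#'
#' @param table a balanced [yield_table()] (equal replicates per
#'   method x sample x block cell).
#' @return an `anova_table` data frame with columns `source`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p`, `error_stratum`.
#' @export
splitplot_anova <- function(table) {
  stopifnot(inherits(table, "yield_table"))
  if (!attr(table, "log_transformed")) table <- log_transform_yields(table)
  df <- as.data.frame(table)
  df$block <- block_label(table)

  counts <- table(df$method, df$sample, df$block)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0)) {
    stop("unbalanced design: equal replication per method x sample x block ",
         "is required; subset the data to a balanced core first")
  }
  r <- unique(as.vector(counts))
  M <- length(unique(df$method)); S <- length(unique(df$sample))
  B <- length(unique(df$block)); N <- nrow(df)
  y <- df$concentration
  gm <- mean(y)

  mean_by <- function(...) tapply(y, list(...), mean)
  mb <- mean_by(df$block)
  mm <- mean_by(df$method)
  ms <- mean_by(df$sample)
  mmb <- mean_by(df$method, df$block)
  mms <- mean_by(df$method, df$sample)

  ss_total <- sum((y - gm)^2)
  ss_block <- M * S * r * sum((mb - gm)^2)
  ss_method <- S * B * r * sum((mm - gm)^2)
  dev_mb <- matrix(0, M, B)
  for (i in seq_len(M)) for (j in seq_len(B)) {
    dev_mb[i, j] <- mmb[i, j] - mm[i] - mb[j] + gm
  }
  ss_wpe <- S * r * sum(dev_mb^2)
  ss_sample <- M * B * r * sum((ms - gm)^2)
  dev_ms <- matrix(0, M, S)
  for (i in seq_len(M)) for (j in seq_len(S)) {
    dev_ms[i, j] <- mms[i, j] - mm[i] - ms[j] + gm
  }
  ss_int <- B * r * sum(dev_ms^2)
  ss_resid <- ss_total - ss_block - ss_method - ss_wpe - ss_sample - ss_int
  ss_resid <- max(ss_resid, 0)

  dfs <- c(block = B - 1, method = M - 1, wpe = (B - 1) * (M - 1),
           sample = S - 1, int = (M - 1) * (S - 1))
  df_resid <- (N - 1) - sum(dfs)
  if (df_resid < 1) stop("no residual degrees of freedom; need replication")

  src <- data.frame(
    source = c("block", "method", "block:method", "sample", "method:sample",
               "residual"),
    df = c(dfs, df_resid),
    sum_sq = c(ss_block, ss_method, ss_wpe, ss_sample, ss_int, ss_resid),
    stringsAsFactors = FALSE)
  src$mean_sq <- src$sum_sq / src$df
  ms_wpe <- src$mean_sq[src$source == "block:method"]
  ms_res <- src$mean_sq[src$source == "residual"]
  src$F <- NA_real_
  src$p <- NA_real_
  src$error_stratum <- c(NA, "block:method", NA, "residual", "residual", NA)
  f_of <- function(row, denom_ms, denom_df) {
    f <- src$mean_sq[row] / denom_ms
    c(f, pf(f, src$df[row], denom_df, lower.tail = FALSE))
  }
  i <- which(src$source == "method")
  src[i, c("F", "p")] <- f_of(i, ms_wpe, src$df[src$source == "block:method"])
  i <- which(src$source == "sample")
  src[i, c("F", "p")] <- f_of(i, ms_res, df_resid)
  i <- which(src$source == "method:sample")
  src[i, c("F", "p")] <- f_of(i, ms_res, df_resid)
  class(src) <- c("anova_table", "data.frame")
  src
}

#' Tukey HSD pairwise comparison of methods for one sample
#'
#' One-way layout on log yields for the chosen sample: every method pair
#' is declared significant when the absolute difference of mean log
#' yields exceeds `qtukey(1 - alpha, k, df) * sqrt(MS_within / n)`.
#' Tukey-adjusted p-values come from the studentized range distribution.
#' (The per-sample one-way error term is used rather than the global
#' split-plot residual, making each table self-contained.)
#'
#' @param table a [yield_table()].
#' @param sample sample label to analyse.
#' @param alpha family-wise significance level.
#' @return list with `sample`, `means` (raw-scale means, for display),
#'   `log_means`, `n`, `df`, `ms_within`, `p_values` and `significant`
#'   (symmetric matrices), `alpha`.
#' @export
tukey_hsd_per_sample <- function(table, sample, alpha = 0.05) {
  stopifnot(inherits(table, "yield_table"))
  raw <- as.data.frame(table)[as.data.frame(table)$sample == sample, ,
                              drop = FALSE]
  if (nrow(raw) == 0) stop("no records for sample ", sample)
  logt <- attr(table, "log_transformed")
  conc_raw <- if (logt) exp(raw$concentration) else raw$concentration
  y <- if (logt) raw$concentration else log(raw$concentration)
  g <- factor(raw$method)
  k <- nlevels(g)
  if (k < 2) stop("need at least two methods for sample ", sample)
  n_per <- tabulate(g)
  if (length(unique(n_per)) != 1) {
    stop("unequal replication per method for sample ", sample)
  }
  n <- n_per[1]
  if (n < 2) stop("need within-group replication (n >= 2) per method")
  means_log <- tapply(y, g, mean)
  df_w <- length(y) - k
  ms_within <- sum((y - means_log[g])^2) / df_w
  se <- sqrt(ms_within / n)
  qcrit <- qtukey(1 - alpha, k, df_w)
  diffs <- abs(outer(means_log, means_log, "-"))
  if (ms_within == 0) {
    pmat <- ifelse(diffs > 0, 0, 1)
    sig <- diffs > 0
  } else {
    pmat <- ptukey(diffs / se, k, df_w, lower.tail = FALSE)
    sig <- diffs > qcrit * se
  }
  diag(pmat) <- 1
  diag(sig) <- FALSE
  means_raw <- tapply(conc_raw, g, mean)
  list(sample = sample, means = means_raw, log_means = means_log,
       n = n, df = df_w, ms_within = ms_within,
       p_values = pmat, significant = sig, alpha = alpha)
}

#' Compact letter display
#'
#' Summarizes an all-pairs significance matrix with letters such that two
#' treatments share at least one letter **iff** their comparison is
#' non-significant (insert-and-absorb construction). Treatments are
#' ordered by descending mean; letters are assigned `A`, `B`, ... in
#' first-use order, so the treatment with the largest mean always carries
#' `A`.
#'
#' @param pairwise symmetric logical matrix, `TRUE` = significantly
#'   different; dimnames give the treatment labels.
#' @param means named numeric vector of treatment means (display order).
#' @return a `letter_display` list: `letters` (named character vector, in
#'   descending-mean order), `groups` (list of letter membership sets),
#'   `pairwise` (the input matrix).
#' @export
compact_letter_display <- function(pairwise, means) {
  pairwise <- as.matrix(pairwise)
  if (!isTRUE(all.equal(pairwise, t(pairwise)))) {
    stop("pairwise significance matrix must be symmetric")
  }
  labs <- rownames(pairwise)
  if (is.null(labs)) labs <- names(means)
  if (is.null(labs)) stop("treatments must be labelled")
  dimnames(pairwise) <- list(labs, labs)
  if (!setequal(labs, names(means))) {
    stop("means and pairwise matrix must cover the same treatments")
  }
  ord <- labs[order(-means[labs])]
  # insert-and-absorb: start from one all-inclusive column, split on each
  # significant pair, absorb columns that became subsets of another
  cols <- list(ord)
  pairs_idx <- which(upper.tri(pairwise) & pairwise, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs_idx))) {
    a <- labs[pairs_idx[r, 1]]; b <- labs[pairs_idx[r, 2]]
    new_cols <- list()
    for (col in cols) {
      if (all(c(a, b) %in% col)) {
        new_cols <- c(new_cols, list(setdiff(col, a)), list(setdiff(col, b)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    new_cols <- new_cols[lengths(new_cols) > 0]
    # absorb: drop any column contained in another (duplicates keep the first)
    keep <- rep(TRUE, length(new_cols))
    for (i in seq_along(new_cols)) {
      for (j in seq_along(new_cols)) {
        if (i == j || !keep[i]) next
        if (all(new_cols[[i]] %in% new_cols[[j]]) &&
            (length(new_cols[[i]]) < length(new_cols[[j]]) ||
             (length(new_cols[[i]]) == length(new_cols[[j]]) && i > j && keep[j]))) {
          keep[i] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by the best (largest) mean they contain, so 'A' goes to
  # the top-mean group
  best <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(-best)]
  letters_out <- setNames(rep("", length(ord)), ord)
  for (i in seq_along(cols)) {
    l <- LETTERS[i]
    for (trt in cols[[i]]) {
      letters_out[trt] <- paste0(letters_out[trt], l)
    }
  }
  # letters within a treatment sorted alphabetically for stable display
  letters_out[] <- vapply(strsplit(letters_out, ""), function(ch)
    paste(sort(ch), collapse = ""), character(1))
  structure(list(letters = letters_out, groups = cols, pairwise = pairwise,
                 means = means[ord]),
            class = "letter_display")
}

#' @export
print.letter_display <- function(x, ...) {
  df <- data.frame(treatment = names(x$letters),
                   mean = round(unname(x$means[names(x$letters)]), 3),
                   letters = unname(x$letters))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Check the letter-display invariant
#'
#' Two treatments share a letter iff their pairwise comparison is
#' non-significant. Used by the property tests and exported because it is
#' the definition of a valid display.
#'
#' @param display a `letter_display`.
#' @return `TRUE` if the invariant holds, otherwise `FALSE`.
#' @export
letters_consistent <- function(display) {
  lab <- names(display$letters)
  sets <- strsplit(display$letters, "")
  names(sets) <- lab
  for (i in seq_along(lab)) {
    for (j in seq_along(lab)) {
      if (i >= j) next
      share <- length(intersect(sets[[i]], sets[[j]])) > 0
      sig <- display$pairwise[lab[i], lab[j]]
      if (share == sig) return(FALSE)
    }
  }
  TRUE
}

#' Headline yield summaries
#'
#' Given per-method x per-sample mean concentrations (either a summary
#' data frame `method`/`sample`/`concentration` of means, or a full
#' [yield_table()] which is averaged first), computes for every sample:
#' the method ranking, the fold ratio of the top method's mean over the
#' best *other* method's mean ("at least x-fold higher"), and a tally of
#' how many samples each method is lowest in. Fold ratios are reported
#' rounded half-up to 1 decimal place alongside full precision.
#'
#' @param table a [yield_table()] or a data frame of means.
#' @return a `yield_summary` list: `per_sample` (list with `ranking`,
#'   `top_method`, `fold_ratio`, `fold_ratio_1dp`, `ties`),
#'   `lowest_counts` (named integer vector), `n_samples`.
#' @export
yield_summary <- function(table) {
  df <- as.data.frame(table)
  if (!all(c("method", "sample", "concentration") %in% names(df))) {
    stop("need columns method, sample, concentration")
  }
  means <- aggregate(concentration ~ method + sample, df, mean)
  wide <- tapply(means$concentration, list(means$sample, means$method), mean)
  if (anyNA(wide)) {
    stop("missing method x sample cells: every method must appear in every sample")
  }
  samples <- rownames(wide)
  methods <- colnames(wide)
  per_sample <- lapply(samples, function(s) {
    v <- wide[s, ]
    ord <- order(-v)
    top <- methods[ord[1]]
    best_other <- max(v[methods != top])
    ties_top <- methods[v == v[ord[1]]]
    fr <- v[ord[1]] / best_other
    list(sample = s,
         ranking = methods[ord],
         top_method = top,
         fold_ratio = unname(fr),
         fold_ratio_1dp = unname(round_half_up(fr, 1)),
         ties = if (length(ties_top) > 1) ties_top else character(0),
         lowest_method = methods[which.min(v)])
  })
  names(per_sample) <- samples
  lowest <- vapply(per_sample, function(x) x$lowest_method, character(1))
  lowest_counts <- setNames(integer(length(methods)), methods)
  tab <- table(lowest)
  lowest_counts[names(tab)] <- as.integer(tab)
  structure(list(per_sample = per_sample, lowest_counts = lowest_counts,
                 n_samples = length(samples), means = wide),
            class = "yield_summary")
}

#' @export
print.yield_summary <- function(x, ...) {
  cat("Yield summary over", x$n_samples, "samples\n")
  for (s in names(x$per_sample)) {
    ps <- x$per_sample[[s]]
    cat(sprintf("  %-35s top: %-8s fold vs best other: %.1f\n",
                s, ps$top_method, ps$fold_ratio_1dp))
  }
  cat("Lowest-mean tallies:\n")
  print(x$lowest_counts)
  invisible(x)
}
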