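# Count tables: taxa x replicate read counts with replicate metadata.

#' Build a count table
#'
#' A count table holds non-negative integer read counts with taxa as rows
#' and replicates as columns, plus optional per-replicate metadata
#' (method, experimenter, day). Metadata is mandatory only for
#' reproducibility analyses that compare blocks; goodness-of-fit and
#' representation scoring need counts alone.
#'
#' @param counts integer matrix (taxa x replicates). Row names are taxon
#'   labels; column names are replicate ids (defaults `rep1`, `rep2`, ...).
#' @param meta optional data frame with columns `replicate_id`, `method`,
#'   `experimenter`, `day`; `replicate_id` must match the column names.
#' @return a `count_table` object (list with elements `counts`, `meta`).
#' @export
count_table <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (anyNA(counts) || any(!is_whole(counts)) || any(counts < 0)) {
    bad <- which(is.na(counts) | !is_whole(counts) | counts < 0, arr.ind = TRUE)
    stop("counts must be non-negative integers; first offending cell: row ",
         bad[1, 1], ", column ", bad[1, 2])
  }
  storage.mode(counts) <- "double"  # exact for counts < 2^53, avoids int overflow
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("taxon", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("rep", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("replicate ids must be unique")
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"replicate_id" %in% names(meta)) {
      stop("meta must contain a replicate_id column")
    }
    if (anyDuplicated(meta$replicate_id)) {
      stop("meta replicate_id values must be unique")
    }
    if (!setequal(meta$replicate_id, colnames(counts))) {
      stop("meta replicate_id values must match count table columns")
    }
    meta <- meta[match(colnames(counts), meta$replicate_id), , drop = FALSE]
    rownames(meta) <- NULL
    for (f in c("method", "experimenter", "day")) {
      if (is.null(meta[[f]])) meta[[f]] <- NA_character_
      meta[[f]] <- as.character(meta[[f]])
    }
    meta <- meta[, c("replicate_id", "method", "experimenter", "day")]
  }
  structure(list(counts = counts, meta = meta), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("Count table:", nrow(x$counts), "taxa x", ncol(x$counts), "replicates",
      if (is.null(x$meta)) "(no metadata)" else "(with metadata)", "\n")
  print(head(x$counts, 12))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Per-replicate observed proportions
#'
#' Normalizes each replicate column by its total read count. Zero-count
#' taxa keep proportion 0 — no pseudocounts are added anywhere in the
#' package; the goodness-of-fit likelihood handles zeros natively.
#'
#' @param table a [count_table()].
#' @return numeric matrix (taxa x replicates); each column sums to 1.
#' @export
observed_proportions <- function(table) {
  stopifnot(inherits(table, "count_table"))
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("replicate(s) with zero total reads: ",
         paste(colnames(table$counts)[totals == 0], collapse = ", "))
  }
  sweep(table$counts, 2, totals, "/")
}

#' Grand (pooled) proportions
#'
#' Pools counts per taxon across all replicates and then normalizes.
#' This is *not* the mean of per-replicate proportions: replicates with
#' more reads carry proportionally more weight, which is the intended
#' baseline for reproducibility scoring.
#'
#' @param table a [count_table()].
#' @return named numeric vector of proportions summing to 1.
#' @export
grand_proportions <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (ncol(table$counts) == 0) stop("count table has no replicates")
  pooled <- rowSums(table$counts)
  if (sum(pooled) == 0) stop("count table has no reads")
  p <- pooled / sum(pooled)
  validate_proportions(p, "grand proportions")
  p
}

#' Read / write a count table as TSV
#'
#' The format is a plain TSV with first column `taxon` and one column per
#' replicate, preceded by optional metadata header lines of the form
#' `#meta<TAB>replicate_id<TAB>method<TAB>experimenter<TAB>day` (one per
#' replicate). The round trip `write_count_table()` then
#' [read_count_table()] is lossless, including metadata.
#'
#' @param path file path.
#' @param community optional [mock_community()]; if supplied, the file's
#'   taxa must match its taxa exactly (same set and order).
#' @return a [count_table()].
#' @export
read_count_table <- function(path, community = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#meta\t", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  df <- read.delim(text = paste(body, collapse = "\n"), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "taxon") stop("first column must be 'taxon'")
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$taxon
  meta <- NULL
  if (length(meta_lines)) {
    parts <- strsplit(meta_lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 5)) {
      stop("malformed #meta line; expected 5 tab-separated fields")
    }
    meta <- data.frame(do.call(rbind, lapply(parts, function(p) p[2:5])),
                       stringsAsFactors = FALSE)
    names(meta) <- c("replicate_id", "method", "experimenter", "day")
  }
  if (!is.null(community)) {
    if (!identical(rownames(counts), community$name)) {
      stop("taxa in count table do not match the supplied community ",
           "(same names in the same order required)")
    }
  }
  count_table(counts, meta)
}

#' @rdname read_count_table
#' @param table a [count_table()].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(table$meta)) {
    for (i in seq_len(nrow(table$meta))) {
      writeLines(paste(c("#meta", unlist(table$meta[i, ])), collapse = "\t"),
                 con)
    }
  }
  df <- data.frame(taxon = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
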