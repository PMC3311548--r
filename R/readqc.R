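# Amplicon read QC: barcode demultiplexing, degenerate primer matching,
# length / ambiguity / homopolymer filters.
#
# Read layout assumed on input (as produced by barcoded amplicon
# sequencing after adapter removal, and by simulate_reads()):
#   [8 bp barcode][2 bp linker][forward primer][template ...]

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Commonly used degenerate forward primers for the 16S V1-V2 region
#'
#' `27f_CM` (`AGAGTTTGATCMTGGCTCAG`, M = A/C) and the fourfold-degenerate
#' `27f_YM` (`AGAGTTTGATYMTGGCTCAG`, Y = C/T); mixtures of these reduce
#' amplification bias between *Lactobacillus* and *Gardnerella*.
#'
#' @return named character vector of IUPAC primer strings.
#' @export
primer_set_27f <- function() {
  c(`27f_CM` = "AGAGTTTGATCMTGGCTCAG",
    `27f_YM` = "AGAGTTTGATYMTGGCTCAG")
}

#' Read-filtering policy
#'
#' Defaults follow common 454-era practice: keep reads of at least 100 bp
#' after trimming, allow at most 1 barcode mismatch, at most 2 primer
#' mismatches, fewer than 2 ambiguous bases and homopolymer runs shorter
#' than 7 bp.
#'
#' @param min_length minimum post-trim length.
#' @param max_barcode_hamming maximum Hamming distance for barcode
#'   assignment.
#' @param max_primer_mismatch maximum primer mismatches.
#' @param max_ambiguous maximum allowed count of `N` bases (inclusive).
#' @param max_homopolymer maximum allowed homopolymer run (inclusive).
#' @return a `filter_policy` list.
#' @export
filter_policy <- function(min_length = 100, max_barcode_hamming = 1,
                          max_primer_mismatch = 2, max_ambiguous = 1,
                          max_homopolymer = 6) {
  vals <- c(min_length, max_barcode_hamming, max_primer_mismatch,
            max_ambiguous, max_homopolymer)
  if (any(vals < 0) || any(!is_whole(vals))) {
    stop("policy thresholds must be non-negative integers")
  }
  structure(list(min_length = min_length,
                 max_barcode_hamming = max_barcode_hamming,
                 max_primer_mismatch = max_primer_mismatch,
                 max_ambiguous = max_ambiguous,
                 max_homopolymer = max_homopolymer),
            class = "filter_policy")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Assign a read to a barcode
#'
#' Compares the read's prefix against every barcode and assigns the label
#' of the *unique* barcode within `max_dist` Hamming distance. Zero or
#' two-plus candidates within range give `NA`: ambiguity is never
#' guessed.
#'
#' @param observed read sequence (or bare prefix).
#' @param barcodes named character vector, label -> barcode; all barcodes
#'   must share one length.
#' @param max_dist maximum Hamming distance.
#' @return barcode label, or `NA_character_` if unassigned.
#' @export
assign_barcode <- function(observed, barcodes, max_dist = 1) {
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1) stop("all barcodes must have the same length")
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    stop("barcodes must be a named vector (label -> sequence)")
  }
  if (nchar(observed) < bl) return(NA_character_)
  prefix <- substr(observed, 1, bl)
  d <- vapply(barcodes, function(b) hamming(prefix, b), numeric(1))
  hit <- which(d <= max_dist)
  if (length(hit) != 1) return(NA_character_)
  names(barcodes)[hit]
}

# Mismatch count of a concrete sequence against one IUPAC primer at
# position 1; a degenerate code matches any base of its expansion with
# zero penalty.
iupac_mismatches <- function(sequence, primer) {
  pl <- nchar(primer)
  if (nchar(sequence) < pl) return(Inf)
  s <- strsplit(substr(sequence, 1, pl), "")[[1]]
  p <- strsplit(primer, "")[[1]]
  ok <- mapply(function(base, code) {
    exp <- IUPAC_EXPAND[[code]]
    if (is.null(exp)) stop("invalid IUPAC code in primer: ", code)
    base %in% exp
  }, s, p)
  sum(!ok)
}

#' Match a sequence against a set of degenerate primers
#'
#' IUPAC-aware comparison at the start of the sequence (the expected
#' primer position after barcode/linker removal). The best-matching
#' primer (fewest mismatches) is reported; `matched` is `TRUE` when that
#' count is within `max_mismatch`.
#'
#' @param sequence DNA string beginning at the expected primer position.
#' @param primers named character vector of IUPAC primer strings (see
#'   [primer_set_27f()]).
#' @param max_mismatch maximum tolerated mismatches.
#' @return list with `matched`, `primer` (label of best primer),
#'   `mismatches`.
#' @export
match_primer <- function(sequence, primers, max_mismatch = 2) {
  if (length(primers) == 0) stop("primer set is empty")
  if (is.null(names(primers))) names(primers) <- primers
  mm <- vapply(primers, function(p) iupac_mismatches(sequence, p), numeric(1))
  best <- which.min(mm)
  list(matched = is.finite(mm[best]) && mm[best] <= max_mismatch,
       primer = names(primers)[best],
       mismatches = unname(mm[best]))
}

#' Longest homopolymer run
#'
#' @param sequence non-empty DNA string.
#' @return length of the longest run of a single repeated base.
#' @export
longest_homopolymer <- function(sequence) {
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  max(rle(strsplit(sequence, "")[[1]])$lengths)
}

#' Filter barcoded amplicon reads
#'
#' Applies, in order: barcode assignment, primer match, post-trim length,
#' ambiguous-base count, homopolymer run. Each rejected read logs the
#' *first* failing rule (the kept set does not depend on rule order, only
#' the logged reasons do). Kept reads are trimmed of barcode + linker +
#' primer. The barcode and/or primer stages can be disabled with `NULL`,
#' e.g. to re-filter already-trimmed reads. An optional `external_pass`
#' vector (named by read id) lets a pipeline impose additional per-read
#' pass/fail decisions (e.g. alignment-position criteria computed
#' elsewhere).
#'
#' @param reads data frame with columns `id`, `sequence` (and optional
#'   `quality`, carried through untouched), e.g. from [read_fastq()].
#' @param barcodes named barcode vector, or `NULL` to skip demultiplexing.
#' @param primers named IUPAC primer vector, or `NULL` to skip primer
#'   matching/trimming.
#' @param policy a [filter_policy()].
#' @param linker linker between barcode and primer (default `"TC"`),
#'   trimmed with the primer.
#' @param external_pass optional named logical vector of extra per-read
#'   verdicts; `FALSE` rejects with reason `"external"`.
#' @return list with `kept` (data frame: `id`, `barcode`, `sequence`,
#'   `quality`) and `log` (data frame: `id`, `kept`, `reason`).
#' @export
filter_reads <- function(reads, barcodes, primers, policy = filter_policy(),
                         linker = "TC", external_pass = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence") %in% names(reads))) {
    stop("reads must have columns id and sequence")
  }
  if (is.null(reads$quality)) reads$quality <- NA_character_
  n <- nrow(reads)
  kept <- vector("list", n)
  log_reason <- character(n)
  log_kept <- logical(n)
  bl <- if (!is.null(barcodes)) unique(nchar(barcodes)) else 0

  for (i in seq_len(n)) {
    id <- reads$id[i]
    seqn <- toupper(reads$sequence[i])
    qual <- reads$quality[i]
    if (!nzchar(seqn) || grepl("[^ACGTN]", seqn)) {
      log_reason[i] <- "unreadable"
      next
    }
    label <- NA_character_
    if (!is.null(barcodes)) {
      label <- assign_barcode(seqn, barcodes, policy$max_barcode_hamming)
      if (is.na(label)) {
        log_reason[i] <- "barcode"
        next
      }
      trim_at <- bl + nchar(linker)
      seqn <- substr(seqn, trim_at + 1, nchar(seqn))
      if (!is.na(qual)) qual <- substr(qual, trim_at + 1, nchar(qual))
    }
    if (!is.null(primers)) {
      pm <- match_primer(seqn, primers, policy$max_primer_mismatch)
      if (!pm$matched) {
        log_reason[i] <- "primer"
        next
      }
      pl <- nchar(primers[[pm$primer]])
      seqn <- substr(seqn, pl + 1, nchar(seqn))
      if (!is.na(qual)) qual <- substr(qual, pl + 1, nchar(qual))
    }
    if (nchar(seqn) < policy$min_length) {
      log_reason[i] <- "length"
      next
    }
    if (lengths(regmatches(seqn, gregexpr("N", seqn, fixed = TRUE))) >
        policy$max_ambiguous) {
      log_reason[i] <- "ambiguous"
      next
    }
    if (longest_homopolymer(seqn) > policy$max_homopolymer) {
      log_reason[i] <- "homopolymer"
      next
    }
    if (!is.null(external_pass) && !is.na(external_pass[id]) &&
        !external_pass[id]) {
      log_reason[i] <- "external"
      next
    }
    log_kept[i] <- TRUE
    log_reason[i] <- "pass"
    kept[[i]] <- data.frame(id = id, barcode = label, sequence = seqn,
                            quality = qual, stringsAsFactors = FALSE)
  }
  kept_df <- if (any(log_kept)) do.call(rbind, kept[log_kept]) else
    data.frame(id = character(0), barcode = character(0),
               sequence = character(0), quality = character(0))
  rownames(kept_df) <- NULL
  list(kept = kept_df,
       log = data.frame(id = reads$id, kept = log_kept, reason = log_reason,
                        stringsAsFactors = FALSE))
}

#' Read / write FASTA and FASTQ
#'
#' Thin wrappers around Biostrings returning/accepting the plain
#' `id`/`sequence`/`quality` data frames used by [filter_reads()].
#'
#' @param path file path.
#' @return data frame with `id`, `sequence` (and `quality` for FASTQ).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  data.frame(id = names(x), sequence = as.character(x),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), sequence = as.character(x),
             quality = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fasta
#' @param reads data frame with `id`, `sequence` (and `quality` for
#'   FASTQ; missing qualities default to `"I"` per base).
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$quality
  if (is.null(qual)) qual <- NA_character_
  qual <- ifelse(is.na(qual),
                 vapply(nchar(reads$sequence),
                        function(n) paste(rep("I", n), collapse = ""),
                        character(1)),
                 qual)
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual))
  invisible(path)
}

#' Read a barcode map TSV
#'
#' Two columns: `label`, `barcode`.
#'
#' @param path file path.
#' @return named character vector, label -> barcode.
#' @export
read_barcode_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("label", "barcode") %in% names(df))) {
    stop("barcode map needs columns 'label' and 'barcode'")
  }
  setNames(toupper(df$barcode), df$label)
}
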