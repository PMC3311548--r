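# Shared small helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in this field are
#' conventionally rounded half up. Used only at the presentation layer —
#' all internal arithmetic stays at full precision.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Format a proportion as a percent
#'
#' @param p proportion(s) in \[0, 1\].
#' @param digits decimal places (default 1, the usual table precision).
#' @return numeric percent value(s), rounded half up.
#' @export
proportion_to_percent <- function(p, digits = 1) {
  round_half_up(100 * p, digits)
}

#' Validate a proportion vector
#'
#' A proportion vector has entries in \[0, 1\] summing to 1 (tolerance
#' 1e-9). Stops with an informative error otherwise.
#'
#' @param values numeric vector.
#' @param what label used in error messages.
#' @return `values`, invisibly.
#' @export
validate_proportions <- function(values, what = "proportions") {
  if (!is.numeric(values) || length(values) == 0) {
    stop(what, " must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(values < -1e-12) || any(values > 1 + 1e-12)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(values) - 1) > 1e-9) {
    stop(what, " must sum to 1 (got ", format(sum(values), digits = 12), ")",
         call. = FALSE)
  }
  invisible(values)
}

# Check that two vectors carry the same taxa in the same order; names are
# mandatory on both sides to prevent silent index misalignment downstream.
check_same_taxa <- function(p, q) {
  if (length(p) != length(q)) {
    stop("vectors have different lengths (", length(p), " vs ", length(q), ")",
         call. = FALSE)
  }
  if (!is.null(names(p)) && !is.null(names(q)) && !identical(names(p), names(q))) {
    stop("taxa labels disagree or are ordered differently", call. = FALSE)
  }
  invisible(TRUE)
}

# Integer-valued check tolerant of numeric storage.
is_whole <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}
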