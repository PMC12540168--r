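#' Normalize free-text tokens for matching
#'
#' Case-folds, strips leading/trailing whitespace, and collapses internal runs
#' of whitespace to a single space. This normalization is applied only at
#' matching time (drug-name lookup, indication and PT comparison, SOC map
#' keys); stored field values are never modified.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
#' @examples
#' normalize_text(c("  Myasthenia   GRAVIS ", "Soliris"))
normalize_text <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

#' Round half away from zero
#'
#' Commercial ("half-up") rounding at a fixed number of decimals, as used in
#' printed percentage cells, in contrast to [base::round()]'s round-half-even.
#' A small epsilon guards against values such as 37.525 being stored as
#' 37.52499999... in binary floating point.
#'
#' @param x numeric vector (non-negative in all package uses).
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop/warn helpers keeping call noise out of user-facing messages
sk_stop <- function(...) stop(..., call. = FALSE)
sk_warn <- function(...) warning(..., call. = FALSE)
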