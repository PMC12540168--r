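#' Parse FAERS partial date tokens
#'
#' FAERS date fields are digit strings of length 4 (`YYYY`), 6 (`YYYYMM`) or
#' 8 (`YYYYMMDD`). This parser is total: tokens of any other shape, months
#' outside 1-12, and day components that do not form a valid calendar date
#' yield a missing row and are tallied, never an error.
#'
#' @param x character vector of raw date tokens (empty strings and `NA`
#'   allowed).
#' @return a [data.table::data.table] with one row per input token and columns
#'   `year`, `month`, `day` (integer, `NA` where absent) and `precision`
#'   (`"year"`, `"month"`, `"day"`, or `NA` for missing/invalid). The number
#'   of non-empty tokens that failed to parse is attached as attribute
#'   `n_invalid`.
#' @export
#' @examples
#' parse_partial_date(c("20240229", "2023", "202313", ""))
parse_partial_date <- function(x) {
  x <- as.character(x)
  n <- length(x)
  out <- data.table(year = NA_integer_, month = NA_integer_,
                    day = NA_integer_, precision = NA_character_)[rep(1L, max(n, 1L))]
  if (n == 0L) return(out[0L])
  tok <- trimws(x)
  tok[is.na(tok)] <- ""
  digits_ok <- grepl("^[0-9]+$", tok)
  len <- nchar(tok)

  yy <- suppressWarnings(as.integer(substr(tok, 1L, 4L)))
  mm <- suppressWarnings(as.integer(substr(tok, 5L, 6L)))
  dd <- suppressWarnings(as.integer(substr(tok, 7L, 8L)))

  is_y <- digits_ok & len == 4L
  is_m <- digits_ok & len == 6L & !is.na(mm) & mm >= 1L & mm <= 12L
  # arithmetic calendar validation (much faster than as.Date on large tables)
  valid_day <- rep(FALSE, n)
  cand <- digits_ok & len == 8L & !is.na(mm) & mm >= 1L & mm <= 12L &
    !is.na(dd) & dd >= 1L & dd <= 31L
  if (any(cand)) {
    dim_month <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
    y <- yy[cand]
    leap <- (y %% 4L == 0L & y %% 100L != 0L) | y %% 400L == 0L
    max_day <- dim_month[mm[cand]] + as.integer(mm[cand] == 2L & leap)
    valid_day[cand] <- dd[cand] <= max_day
  }

  out[is_y, `:=`(year = yy[is_y], precision = "year")]
  out[is_m, `:=`(year = yy[is_m], month = mm[is_m], precision = "month")]
  out[valid_day, `:=`(year = yy[valid_day], month = mm[valid_day],
                      day = dd[valid_day], precision = "day")]
  n_invalid <- sum(tok != "" & is.na(out$precision))
  data.table::setattr(out, "n_invalid", n_invalid)
  out[]
}

#' Numeric sort key for partial dates
#'
#' Maps a date token to `year*10000 + month*100 + day`, zero-filling absent
#' components so that lower-precision dates order before any fully specified
#' date in the same year/month (a conservative "older" reading used by the
#' deduplication rule). Missing or invalid tokens map to 0 and therefore sort
#' before every real date.
#'
#' @param x character vector of raw date tokens.
#' @return numeric vector.
#' @export
partial_date_key <- function(x) {
  pd <- parse_partial_date(x)
  k <- ifelse(is.na(pd$year), 0, pd$year) * 10000 +
    ifelse(is.na(pd$month), 0, pd$month) * 100 +
    ifelse(is.na(pd$day), 0, pd$day)
  as.numeric(k)
}

#' Convert day-precision partial dates to Date
#'
#' @param x character vector of raw date tokens.
#' @return a `Date` vector; `NA` wherever the token is not day-precision.
#' @export
partial_date_as_date <- function(x) {
  pd <- parse_partial_date(x)
  out <- rep(as.Date(NA), nrow(pd))
  i <- !is.na(pd$precision) & pd$precision == "day"
  if (any(i)) {
    out[i] <- as.Date(sprintf("%04d-%02d-%02d", pd$year[i], pd$month[i], pd$day[i]))
  }
  out
}
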