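# Recovering an integer 2x2 contingency table from published statistics.
#
# Published signal tables print, per drug-event pair, the a cell together
# with ROR (and its CI), PRR, chi-squared and IC025, but not b, c, d. Because
# three independent statistics pin three unknowns, the underlying integer
# table can be reconstructed by least squares, after which any statistic not
# used in the fit can be recomputed — a consistency check that also
# adjudicates conventions such as the presence of a continuity correction.

#' Recover a 2x2 table from printed row statistics
#'
#' Solves for integer cells `b, c, d` that best reproduce a published row's
#' statistics, given the printed `a`. Exactly three constraints must be
#' available among: the ROR point estimate, the PRR, the standard error of
#' log ROR implied by the 95% CI (`log(ci_high/ci_low)/(2*1.96)`), and the
#' Pearson chi-squared. The search minimizes the sum of squared log ratios
#' between implied and printed values: a continuous optimization over
#' `log(b), log(c), log(d)` from a grid of starting points, followed by an
#' exhaustive integer refinement in the neighborhood of the continuous
#' optimum.
#'
#' @param a printed report count (the `a` cell).
#' @param ror printed ROR point estimate.
#' @param prr printed PRR.
#' @param ci_low,ci_high printed 95% CI bounds of the ROR (supply both or
#'   neither).
#' @param chi2 printed Pearson chi-squared (no continuity correction).
#' @return list with integer `a, b, c, d`, the achieved `objective`, and
#'   `stats`, a one-row data.table of all statistics recomputed from the
#'   recovered table.
#' @export
#' @examples
#' r <- recover_contingency(5, ror = 10.73, prr = 10.70,
#'                          ci_low = 3.66, ci_high = 31.41)
#' r$stats$chi2
recover_contingency <- function(a, ror = NULL, prr = NULL,
                                ci_low = NULL, ci_high = NULL, chi2 = NULL) {
  se_t <- if (!is.null(ci_low) && !is.null(ci_high)) {
    log(ci_high / ci_low) / (2 * 1.96)
  } else NULL
  n_constraints <- sum(!is.null(ror), !is.null(prr), !is.null(se_t), !is.null(chi2))
  if (n_constraints < 3L) {
    sk_stop("need at least three of {ror, prr, CI, chi2} to recover the table")
  }

  obj <- function(b, c, d) {
    s <- 0
    if (!is.null(ror)) s <- s + log((a * d / (b * c)) / ror)^2
    if (!is.null(prr)) s <- s + log(((a / (a + b)) / (c / (c + d))) / prr)^2
    if (!is.null(se_t)) s <- s + log(sqrt(1 / a + 1 / b + 1 / c + 1 / d) / se_t)^2
    if (!is.null(chi2)) {
      N <- a + b + c + d
      ch <- N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
      s <- s + log(ch / chi2)^2
    }
    s
  }

  ror0 <- ror %||% prr %||% 2
  best <- NULL
  for (b0 in c(10, 100, 1000, 1e4, 1e5)) {
    for (c0 in c(1, 3, 10, 40, 150, 500)) {
      d0 <- max(ror0 * b0 * c0 / a, 1)
      o <- optim(log(c(b0, c0, d0)),
                 function(p) obj(exp(p[1]), exp(p[2]), exp(p[3])),
                 method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  cont <- exp(best$par)
  cand <- expand.grid(b = pmax(1, round(cont[1]) + (-4:4)),
                      c = pmax(1, round(cont[2]) + (-4:4)),
                      d = pmax(1, round(cont[3]) + (-60:60)))
  cand <- unique(cand)
  v <- mapply(obj, cand$b, cand$c, cand$d)
  k <- which.min(v)
  b <- as.integer(cand$b[k]); c <- as.integer(cand$c[k]); d <- as.integer(cand$d[k])

  stats <- cbind(data.table(a = a, b = b, c_ = c, d = d),
                 ror_stats(a, b, c, d), mhra_stats(a, b, c, d),
                 bcpnn_stats(a, b, c, d))
  list(a = as.integer(a), b = b, c = c, d = d,
       objective = v[k], stats = stats)
}
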