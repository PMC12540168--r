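# Disproportionality signal detection on 2x2 contingency tables.
#
# For a drug-event pair the table is
#           event    other events
#   target    a          b
#   other     c          d
# with N = a+b+c+d. Three algorithms are computed per pair: the reporting
# odds ratio with its log-symmetric 95% CI, the MHRA proportional reporting
# ratio with a Pearson chi-squared, and the BCPNN information component with
# its lower credibility bound.

#' Build drug-event contingency tables
#'
#' For every PT observed among a target drug's reports, counts the cells of
#' the 2x2 table against a comparator population. With the default counting
#' unit `"report"`, a report contributes at most once to a PT's `a` cell
#' (duplicated PT rows within one report collapse); with `"pair"`, every
#' report-PT pair is a counting unit and the margins are pair totals.
#'
#' @param assignments assignment table from [select_target_cases()] (columns
#'   `primaryid`, `drug`), or any data.table mapping report ids to a drug
#'   label.
#' @param reac REAC table covering both target and comparator reports.
#' @param universe_ids character vector of all deduplicated report ids in the
#'   loaded window (defines the comparator under `comparator = "window"`).
#' @param comparator `"window"` (all other reports in the loaded window, the
#'   classical background), `"targets"` (reports of the other target drugs),
#'   or `"custom"` (explicit `comparator_ids`).
#' @param comparator_ids report ids for `comparator = "custom"`.
#' @param unit counting unit, `"report"` (default) or `"pair"`.
#' @return data.table `drug, pt, a, b, c_, d` (`c_` avoids masking
#'   [base::c()]); one row per (drug, PT-observed-in-target).
#' @export
build_contingency_tables <- function(assignments, reac, universe_ids,
                                     comparator = c("window", "targets", "custom"),
                                     comparator_ids = NULL,
                                     unit = c("report", "pair")) {
  comparator <- match.arg(comparator)
  unit <- match.arg(unit)
  asg <- unique(as.data.table(assignments)[, .(primaryid, drug)])
  reac <- as.data.table(reac)
  pairs <- reac[, .(primaryid, norm_pt = normalize_text(pt), pt)]
  pairs <- pairs[nzchar(norm_pt)]
  # stable display string per normalized PT
  disp <- pairs[, .(pt = min(pt)), by = norm_pt]
  if (unit == "report") pairs <- unique(pairs[, .(primaryid, norm_pt)])

  out <- list()
  for (dg in sort(unique(asg$drug))) {
    t_ids <- asg[drug == dg, primaryid]
    c_ids <- switch(comparator,
      window = setdiff(universe_ids, t_ids),
      targets = setdiff(asg[drug != dg, primaryid], t_ids),
      custom = setdiff(comparator_ids, t_ids))
    if (length(c_ids) == 0L) sk_stop("empty comparator population for drug ", dg)

    tp <- pairs[primaryid %in% t_ids]
    cp <- pairs[primaryid %in% c_ids]
    t_total <- if (unit == "report") length(t_ids) else nrow(tp)
    c_total <- if (unit == "report") length(c_ids) else nrow(cp)

    a_tab <- tp[, .(a = .N), by = norm_pt]
    c_tab <- cp[, .(c_ = .N), by = norm_pt]
    tab <- c_tab[a_tab, on = "norm_pt"]
    tab[is.na(c_), c_ := 0L]
    tab[, `:=`(b = t_total - a, d = c_total - c_)]
    tab <- disp[tab, on = "norm_pt"]
    out[[dg]] <- tab[, .(drug = dg, pt, a, b, c_, d)]
  }
  res <- rbindlist(out)
  setorder(res, drug, pt)
  res[]
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad / bc` with the log-symmetric Wald interval
#' `exp(log ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`; the point estimate
#' is the geometric mean of the bounds.
#'
#' @param a,b,c,d contingency cells (vectorized).
#' @return data.table `ror, ror_ci_low, ror_ci_high`; `NA` when a zero cell
#'   makes the estimate undefined.
#' @export
ror_stats <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  ok <- a > 0 & b > 0 & c > 0 & d > 0
  ror <- ifelse(ok, (a * d) / (b * c), NA_real_)
  se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
  data.table(ror = ror,
             ror_ci_low = exp(log(ror) - 1.96 * se),
             ror_ci_high = exp(log(ror) + 1.96 * se))
}

#' MHRA statistics: proportional reporting ratio and Pearson chi-squared
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`; the chi-squared statistic is Pearson's
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]` without continuity correction by
#' default (`correction = "yates"` subtracts N/2 from |ad - bc|).
#'
#' @param a,b,c,d contingency cells (vectorized).
#' @param correction `"pearson"` (default) or `"yates"`.
#' @return data.table `prr, chi2`; `prr` is `NA` when `c = 0`.
#' @export
mhra_stats <- function(a, b, c, d, correction = c("pearson", "yates")) {
  correction <- match.arg(correction)
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  prr <- ifelse(a + b > 0 & c > 0 & c + d > 0,
                (a / (a + b)) / (c / (c + d)), NA_real_)
  dev <- abs(a * d - b * c)
  if (correction == "yates") dev <- pmax(dev - N / 2, 0)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- ifelse(denom > 0, N * dev^2 / denom, NA_real_)
  data.table(prr = prr, chi2 = chi2)
}

# BCPNN hyperparameters (the standard choice): independent Beta priors on the
# drug and event margins with alpha1 = beta1 = 1 and alpha = beta = 2, and a
# joint-cell prior gamma11 = 1 with gamma tied to the margins so that the
# prior IC is centred at zero.
bcpnn_posterior_params <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
  gamma <- g11 * (N + al) * (N + be) / ((a + b + a1) * (a + c + b1))
  list(
    p11 = cbind(a + g11, N - a + gamma - g11),
    p1. = cbind(a + b + a1, N - (a + b) + al - a1),
    p.1 = cbind(a + c + b1, N - (a + c) + be - b1),
    gamma = gamma, N = N
  )
}

#' BCPNN information component
#'
#' The information component is `IC = log2 p11 / (p1. p.1)`, the log2
#' observed-to-expected reporting ratio under the BCPNN's Beta/Dirichlet
#' priors. The default `method = "expectation"` returns the exact posterior
#' mean and variance of IC (digamma/trigamma closed forms of the three Beta
#' posteriors); `method = "approx"` returns the classical approximation that
#' plugs posterior means into the log. In both cases
#' `IC025 = IC - 2 sqrt(V(IC))`, the conventional lower credibility bound.
#' The priors regularize zero cells, so the statistic is defined for every
#' table with `N > 0`.
#'
#' @param a,b,c,d contingency cells (vectorized).
#' @param method `"expectation"` (default) or `"approx"`.
#' @return data.table `ic, ic025`.
#' @export
bcpnn_stats <- function(a, b, c, d, method = c("expectation", "approx")) {
  method <- match.arg(method)
  pp <- bcpnn_posterior_params(a, b, c, d)
  ln2 <- log(2)
  if (method == "expectation") {
    e_ln <- function(m) digamma(m[, 1]) - digamma(m[, 1] + m[, 2])
    v_ln <- function(m) trigamma(m[, 1]) - trigamma(m[, 1] + m[, 2])
    ic <- (e_ln(pp$p11) - e_ln(pp$p1.) - e_ln(pp$p.1)) / ln2
    v <- (v_ln(pp$p11) + v_ln(pp$p1.) + v_ln(pp$p.1)) / ln2^2
  } else {
    N <- pp$N; gamma <- pp$gamma
    a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
    ic <- log2((a + g11) * (N + al) * (N + be) /
                 ((N + gamma) * (a + b + a1) * (a + c + b1)))
    v <- ((N - a + gamma - g11) / ((a + g11) * (1 + N + gamma)) +
            (N - (a + b) + al - a1) / ((a + b + a1) * (1 + N + al)) +
            (N - (a + c) + be - b1) / ((a + c + b1) * (1 + N + be))) / ln2^2
  }
  data.table(ic = ic, ic025 = ic - 2 * sqrt(v))
}

#' Monte-Carlo posterior sampler for the BCPNN information component
#'
#' Draws from the three independent Beta posteriors of the BCPNN model and
#' returns samples of `IC = log2 p11/(p1. p.1)`. Serves as a seedable oracle
#' against the closed forms of [bcpnn_stats()].
#'
#' @param a,b,c,d a single contingency table (scalars).
#' @param n_draws number of posterior draws.
#' @param seed optional integer seed (local to this call).
#' @return numeric vector of `n_draws` IC samples (bits).
#' @export
bcpnn_mc <- function(a, b, c, d, n_draws = 1e5, seed = NULL) {
  stopifnot(length(a) == 1L)
  pp <- bcpnn_posterior_params(a, b, c, d)
  draw <- function() {
    p11 <- rbeta(n_draws, pp$p11[, 1], pp$p11[, 2])
    p1. <- rbeta(n_draws, pp$p1.[, 1], pp$p1.[, 2])
    p.1 <- rbeta(n_draws, pp$p.1[, 1], pp$p.1[, 2])
    log2(p11 / (p1. * p.1))
  }
  if (is.null(seed)) draw() else withr_seed(seed, draw())
}

# minimal local-seed evaluation (keeps the caller's RNG state untouched)
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Apply the three signal criteria
#'
#' ROR: `a >= 3` and CI lower bound `> 1`. MHRA: `a >= 3`, `PRR >= 2`,
#' `chi2 >= 4`. BCPNN: `IC025 > 0`. The intersection flag requires all three.
#' Undefined statistics (suppressed zero cells) never flag.
#'
#' @param stats data.table containing `a, ror_ci_low, prr, chi2, ic025`
#'   (e.g. from [signal_stats()]); modified by reference and returned.
#' @return the input with logical columns `flag_ror, flag_mhra, flag_bcpnn,
#'   flag_all3` added.
#' @export
apply_signal_criteria <- function(stats) {
  stats <- as.data.table(stats)
  stats[, flag_ror := !is.na(ror_ci_low) & a >= 3 & ror_ci_low > 1]
  stats[, flag_mhra := !is.na(prr) & !is.na(chi2) & a >= 3 & prr >= 2 & chi2 >= 4]
  stats[, flag_bcpnn := !is.na(ic025) & ic025 > 0]
  stats[, flag_all3 := flag_ror & flag_mhra & flag_bcpnn]
  stats[]
}

#' Compute all disproportionality statistics for a table set
#'
#' Adds ROR/CI, PRR, chi-squared, IC, IC025 and the per-algorithm plus
#' intersection flags to a contingency table set. Zero cells (`b*c = 0`) are
#' handled per `zero_cell`: `"suppress"` (default) leaves ROR/PRR/chi2
#' undefined for those rows, which therefore cannot flag;
#' `"haldane"` adds 0.5 to all four cells of affected rows for the
#' frequentist statistics. BCPNN is always computed (its priors regularize
#' zeros).
#'
#' @param tables data.table from [build_contingency_tables()].
#' @param zero_cell `"suppress"` or `"haldane"`.
#' @param chi2_correction passed to [mhra_stats()].
#' @param ic_method passed to [bcpnn_stats()].
#' @return data.table: the input columns plus all statistics and flags.
#' @export
signal_stats <- function(tables, zero_cell = c("suppress", "haldane"),
                         chi2_correction = c("pearson", "yates"),
                         ic_method = c("expectation", "approx")) {
  zero_cell <- match.arg(zero_cell)
  tab <- copy(as.data.table(tables))
  a <- tab$a; b <- tab$b; c <- tab$c_; d <- tab$d
  if (zero_cell == "haldane") {
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
  }
  tab <- cbind(tab, ror_stats(a, b, c, d),
               mhra_stats(a, b, c, d, correction = chi2_correction),
               bcpnn_stats(tab$a, tab$b, tab$c_, tab$d, method = ic_method))
  apply_signal_criteria(tab)
}

#' Rank positive signals
#'
#' Filters to pairs flagged by all three algorithms and returns the top `n`
#' per drug, ranked by report count or ROR. Ties break on the other key, then
#' on the PT string, making the output byte-stable.
#'
#' @param results flagged statistics table from [signal_stats()].
#' @param by ranking key, `"count"` (the `a` cell) or `"ror"`.
#' @param n rows to keep per drug.
#' @return data.table subset of `results`, ordered.
#' @export
rank_signals <- function(results, by = c("count", "ror"), n = 10L) {
  by <- match.arg(by)
  res <- as.data.table(results)[flag_all3 == TRUE]
  keys <- if (by == "count") c("a", "ror", "pt") else c("ror", "a", "pt")
  setorderv(res, c("drug", keys), order = c(1L, -1L, -1L, 1L))
  res[, head(.SD, n), by = drug]
}

#' Venn region counts of the three algorithms
#'
#' Per drug, the number of PTs in each region of the three-set Venn diagram
#' of the ROR, MHRA and BCPNN flags (PTs flagged by none are excluded).
#'
#' @param results flagged statistics table from [signal_stats()].
#' @return data.table `drug, region, count` with regions `ror_only,
#'   mhra_only, bcpnn_only, ror_mhra, ror_bcpnn, mhra_bcpnn, all3,
#'   any_method`.
#' @export
venn_counts <- function(results) {
  res <- as.data.table(results)
  res[, .(
    ror_only = sum(flag_ror & !flag_mhra & !flag_bcpnn),
    mhra_only = sum(!flag_ror & flag_mhra & !flag_bcpnn),
    bcpnn_only = sum(!flag_ror & !flag_mhra & flag_bcpnn),
    ror_mhra = sum(flag_ror & flag_mhra & !flag_bcpnn),
    ror_bcpnn = sum(flag_ror & !flag_mhra & flag_bcpnn),
    mhra_bcpnn = sum(!flag_ror & flag_mhra & flag_bcpnn),
    all3 = sum(flag_all3),
    any_method = sum(flag_ror | flag_mhra | flag_bcpnn)
  ), by = drug] |>
    data.table::melt(id.vars = "drug", variable.name = "region",
                     value.name = "count", variable.factor = FALSE)
}

#' Stratified signal detection
#'
#' Reruns the contingency/statistics pipeline inside each stratum of a
#' demographic variable (reports with a missing stratum value are excluded
#' and counted). Both the target and the comparator population are restricted
#' to the stratum.
#'
#' @param assignments assignment table from [select_target_cases()].
#' @param tables named list of FAERS tables (deduplicated), needing `demo`
#'   and `reac`.
#' @param stratum `"sex"` or `"occupation"`.
#' @param ... further arguments to [build_contingency_tables()] /
#'   [signal_stats()].
#' @return list with `strata` (named list of flagged statistics tables) and
#'   `n_missing` (reports excluded for a missing stratum value).
#' @export
stratified_signals <- function(assignments, tables,
                               stratum = c("sex", "occupation"), ...) {
  stratum <- match.arg(stratum)
  demo <- as.data.table(tables$demo)
  val <- if (stratum == "sex") {
    v <- toupper(trimws(demo$sex)); v[!v %in% c("F", "M")] <- NA; v
  } else {
    v <- toupper(trimws(demo$occp_cod)); v[!v %in% names(OCCP_LABELS)] <- NA; v
  }
  demo_ids <- split(demo$primaryid, val)
  n_missing <- sum(is.na(val))
  asg <- as.data.table(assignments)
  out <- list()
  for (sv in names(demo_ids)) {
    ids <- demo_ids[[sv]]
    sub_asg <- asg[primaryid %in% ids]
    if (nrow(sub_asg) == 0L) {
      sk_warn("stratum ", stratum, "=", sv, " has no target cases")
      out[[sv]] <- data.table()
      next
    }
    tabs <- build_contingency_tables(sub_asg, as.data.table(tables$reac),
                                     universe_ids = ids, ...)
    out[[sv]] <- signal_stats(tabs)
  }
  list(strata = out, n_missing = n_missing)
}
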