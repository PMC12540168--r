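# Descriptive summaries: demographic characteristic tables, reporting trend,
# onset-time statistics and bins, and SOC rollups of positive-signal PTs.

#' Percentage cell with two decimals
#'
#' `100 * count / total`, rounded half-up at two decimals, the convention of
#' printed characteristic tables. An empty denominator yields `NA` (a blank
#' cell), never an error.
#'
#' @param count,total non-negative counts (vectorized).
#' @return numeric vector.
#' @export
#' @examples
#' percentage(1980, 5276)  # 37.53
percentage <- function(count, total) {
  out <- round_half_up(100 * count / total, 2)
  out[!is.finite(out)] <- NA_real_
  out
}

ONSET_BINS <- c("D0_30", "D31_60", "D61_90", "D90PLUS", "NOT_SPECIFIED")

#' Bin time-to-onset values
#'
#' Partitions onset days into the conventional 0-30 / 31-60 / 61-90 / >90
#' day windows; `NA` maps to `NOT_SPECIFIED`.
#'
#' @param days integer vector of onset days (>= 1 where defined).
#' @return factor with levels `D0_30, D31_60, D61_90, D90PLUS, NOT_SPECIFIED`.
#' @export
bin_onset <- function(days) {
  out <- rep("NOT_SPECIFIED", length(days))
  out[!is.na(days) & days >= 1 & days <= 30] <- "D0_30"
  out[!is.na(days) & days >= 31 & days <= 60] <- "D31_60"
  out[!is.na(days) & days >= 61 & days <= 90] <- "D61_90"
  out[!is.na(days) & days >= 91] <- "D90PLUS"
  factor(out, levels = ONSET_BINS)
}

#' Continuous summary statistics
#'
#' Mean, sample SD (n-1), median, quartiles by linear interpolation between
#' order statistics (quantile type 7), min and max over the non-missing
#' values.
#'
#' @param values numeric vector (may contain `NA`).
#' @return one-row data.table `n, mean, sd, median, q1, q3, min, max`; all
#'   statistics `NA` when no value is available.
#' @export
continuous_summary <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) {
    return(data.table(n = 0L, mean = NA_real_, sd = NA_real_,
                      median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                      min = NA_real_, max = NA_real_))
  }
  q <- unname(quantile(v, c(0.25, 0.75), type = 7))
  data.table(n = length(v), mean = mean(v),
             sd = if (length(v) > 1L) sd(v) else NA_real_,
             median = median(v), q1 = q[1], q3 = q[2],
             min = min(v), max = max(v))
}

#' Reporting trend
#'
#' Counts reports by calendar quarter or year of FDA receipt date.
#'
#' @param fda_dt character vector of raw FDA_DT tokens.
#' @param granularity `"quarter"` or `"year"`.
#' @return data.table `period`, `count`, sorted by period; reports whose
#'   FDA_DT has no parsable year are pooled under period `"unknown"`.
#' @export
trend_counts <- function(fda_dt, granularity = c("quarter", "year")) {
  granularity <- match.arg(granularity)
  pd <- parse_partial_date(fda_dt)
  period <- rep("unknown", nrow(pd))
  has_y <- !is.na(pd$year)
  if (granularity == "year") {
    period[has_y] <- sprintf("%04d", pd$year[has_y])
  } else {
    has_q <- has_y & !is.na(pd$month)
    period[has_q] <- sprintf("%04dQ%d", pd$year[has_q],
                             (pd$month[has_q] - 1L) %/% 3L + 1L)
    period[has_y & !has_q] <- sprintf("%04d", pd$year[has_y & !has_q])
  }
  dt <- data.table(period = period)[, .(count = .N), by = period]
  setorder(dt, period)
  dt[]
}

# AGE_COD conversion factors to years. DEC codes decades (x10); sub-year
# codes divide. Anything else (or a resulting age > 120) is treated missing.
age_to_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  f <- rep(NA_real_, length(a))
  f[cod %in% c("YR", "YEAR", "")] <- 1
  f[cod == "DEC"] <- 10
  f[cod == "MON"] <- 1 / 12
  f[cod == "WK"] <- 1 / 52.18
  f[cod == "DY"] <- 1 / 365.25
  f[cod == "HR"] <- 1 / 8766
  out <- a * f
  out[!is.na(out) & (out > 120 | out < 0)] <- NA_real_
  out
}

weight_to_kg <- function(wt, wt_cod) {
  w <- suppressWarnings(as.numeric(wt))
  cod <- toupper(trimws(wt_cod))
  f <- rep(NA_real_, length(w))
  f[cod %in% c("KG", "KGS", "")] <- 1
  f[cod %in% c("LBS", "LB")] <- 0.45359237
  f[cod == "GMS"] <- 0.001
  out <- w * f
  out[!is.na(out) & out <= 0] <- NA_real_
  out
}

AGE_BANDS <- c("<18", "18-44", "45-64", "65-74", ">=75", "Not specified")

age_band <- function(years) {
  out <- rep("Not specified", length(years))
  out[!is.na(years) & years < 18] <- "<18"
  out[!is.na(years) & years >= 18 & years < 45] <- "18-44"
  out[!is.na(years) & years >= 45 & years < 65] <- "45-64"
  out[!is.na(years) & years >= 65 & years < 75] <- "65-74"
  out[!is.na(years) & years >= 75] <- ">=75"
  factor(out, levels = AGE_BANDS)
}

OCCP_LABELS <- c(CN = "Consumer", PH = "Pharmacist", MD = "Physician",
                 LW = "Lawyer", HP = "Healthcare Professional")

block_rows <- function(drug_name, block, labels, counts, total) {
  data.table(drug = drug_name, block = block, label = labels,
             count = as.integer(counts), total = as.integer(total),
             percent = percentage(counts, total))
}

#' Characteristics table for assigned cases
#'
#' Builds the per-drug demographic/clinical characteristics table: sex, age
#' bands and continuous age, weight, reporter occupation, reporter country,
#' seriousness, serious-outcome codes, onset bins and continuous onset. Each
#' categorical block's counts sum to the drug's report total; percentages use
#' [percentage()]. Seriousness is operationalized as "has at least one
#' outcome code", the standard reading when no explicit flag is distributed.
#'
#' @param assignments assignment table from [select_target_cases()].
#' @param tables named list of FAERS tables (deduplicated).
#' @param onset optional data.table from [case_onset_days()]; computed when
#'   omitted.
#' @return list with `categorical` (data.table `drug, block, label, count,
#'   total, percent`) and `continuous` (data.table of per-drug
#'   [continuous_summary()] rows for age, weight and onset, column
#'   `variable`).
#' @export
characteristics_table <- function(assignments, tables, onset = NULL) {
  asg <- unique(as.data.table(assignments)[, .(primaryid, drug)])
  demo <- as.data.table(tables$demo)
  outc <- as.data.table(tables$outc)
  if (is.null(onset)) onset <- case_onset_days(assignments, tables)

  cat_rows <- list()
  cont_rows <- list()
  for (dg in sort(unique(asg$drug))) {
    ids <- asg[drug == dg, primaryid]
    dd <- demo[primaryid %in% ids]
    total <- length(ids)

    sex <- toupper(trimws(dd$sex %||% rep("", nrow(dd))))
    sex[!sex %in% c("F", "M")] <- "Not specified"
    sex <- factor(sex, levels = c("F", "M", "Not specified"))
    cat_rows[[length(cat_rows) + 1L]] <-
      block_rows(dg, "sex", levels(sex), tabulate(sex, 3L), total)

    ages <- age_to_years(dd$age, dd$age_cod)
    ab <- age_band(ages)
    cat_rows[[length(cat_rows) + 1L]] <-
      block_rows(dg, "age_band", levels(ab), tabulate(ab, length(AGE_BANDS)), total)
    cont_rows[[length(cont_rows) + 1L]] <-
      cbind(data.table(drug = dg, variable = "age_years"), continuous_summary(ages))

    wt <- weight_to_kg(dd$wt, dd$wt_cod)
    cont_rows[[length(cont_rows) + 1L]] <-
      cbind(data.table(drug = dg, variable = "weight_kg"), continuous_summary(wt))

    occ <- toupper(trimws(dd$occp_cod %||% rep("", nrow(dd))))
    occ_lab <- unname(OCCP_LABELS[occ])
    occ_lab[is.na(occ_lab)] <- "Not specified"
    occ <- factor(occ_lab, levels = c(unname(OCCP_LABELS), "Not specified"))
    cat_rows[[length(cat_rows) + 1L]] <-
      block_rows(dg, "occupation", levels(occ), tabulate(occ, nlevels(occ)), total)

    ctry <- trimws(dd$reporter_country %||% rep("", nrow(dd)))
    ctry[!nzchar(ctry)] <- "Not specified"
    tab <- sort(table(ctry), decreasing = TRUE)
    cat_rows[[length(cat_rows) + 1L]] <-
      block_rows(dg, "country", names(tab), as.integer(tab), total)

    serious_ids <- unique(outc[primaryid %in% ids, primaryid])
    n_serious <- length(serious_ids)
    cat_rows[[length(cat_rows) + 1L]] <-
      block_rows(dg, "seriousness", c("Serious", "Non-serious"),
                 c(n_serious, total - n_serious), total)

    oc <- outc[primaryid %in% ids]
    if (nrow(oc) > 0L) {
      oc_tab <- oc[, .(count = uniqueN(primaryid)), by = .(label = toupper(trimws(outc_cod)))]
      cat_rows[[length(cat_rows) + 1L]] <-
        data.table(drug = dg, block = "outcome", label = oc_tab$label,
                   count = oc_tab$count, total = total,
                   percent = percentage(oc_tab$count, total))
    }

    ons <- onset[drug == dg]
    ons <- ons[match(ids, primaryid), onset]
    ob <- bin_onset(ons)
    cat_rows[[length(cat_rows) + 1L]] <-
      block_rows(dg, "onset_bin", levels(ob), tabulate(ob, length(ONSET_BINS)), total)
    cont_rows[[length(cont_rows) + 1L]] <-
      cbind(data.table(drug = dg, variable = "onset_days"), continuous_summary(ons))
  }
  if (length(cat_rows) == 0L) {
    return(list(
      categorical = data.table(drug = character(0), block = character(0),
                               label = character(0), count = integer(0),
                               total = integer(0), percent = numeric(0)),
      continuous = cbind(data.table(drug = character(0), variable = character(0)),
                         continuous_summary(numeric(0))[0])))
  }
  list(categorical = rbindlist(cat_rows), continuous = rbindlist(cont_rows))
}

#' Roll positive-signal PTs up to system organ classes
#'
#' Each PT contributes its report count to exactly one primary SOC; PTs
#' absent from the map are pooled under the sentinel `UNMAPPED_SOC`, so total
#' report mass is conserved.
#'
#' @param positive_pts data.table/data.frame with columns `pt` and `reports`
#'   (report count per PT); an optional `drug` column keeps drugs separate.
#' @param soc_map a [load_soc_map()] result.
#' @return data.table `(drug,) soc, reports` sorted by descending reports.
#' @export
soc_rollup <- function(positive_pts, soc_map) {
  dt <- as.data.table(positive_pts)
  if (nrow(dt) == 0L) {
    return(data.table(soc = character(0), reports = integer(0)))
  }
  dt[, soc := map_pt_to_soc(pt, soc_map)]
  by_cols <- intersect(c("drug", "soc"), names(dt))
  out <- dt[, .(reports = sum(reports)), by = by_cols]
  setorderv(out, c(setdiff(by_cols, "soc"), "reports"),
            order = c(rep(1L, length(by_cols) - 1L), -1L))
  out[]
}

#' Onset-bin histogram per signal PT
#'
#' Maps reports that provided an onset time to the PTs they contain, giving a
#' per-(drug, PT) histogram over the onset bins. Only reports with a defined
#' onset are counted, so each PT's histogram totals the number of its reports
#' with known onset.
#'
#' @param signal_pts data.table/data.frame with columns `drug`, `pt` naming
#'   the PTs of interest.
#' @param reac REAC table (deduplicated).
#' @param onset data.table from [case_onset_days()].
#' @return data.table `drug, pt, bin, count` over the four day bins.
#' @export
pt_onset_profile <- function(signal_pts, reac, onset) {
  sp <- unique(as.data.table(signal_pts)[, .(drug, pt)])
  reac <- as.data.table(reac)
  ons <- as.data.table(onset)[!is.na(onset)]
  pairs <- unique(reac[, .(primaryid, norm_pt = normalize_text(pt))])
  sp[, norm_pt := normalize_text(pt)]
  joined <- pairs[ons, on = "primaryid", nomatch = NULL, allow.cartesian = TRUE]
  joined <- joined[sp, on = c("drug", "norm_pt"), nomatch = NULL]
  grid <- sp[, .(bin = factor(ONSET_BINS[1:4], levels = ONSET_BINS[1:4])),
             by = .(drug, pt)]
  if (nrow(joined) == 0L) {
    grid[, count := 0L]
    return(grid[])
  }
  joined[, bin := bin_onset(onset)]
  counts <- joined[, .(count = .N), by = .(drug, norm_pt, bin)]
  counts <- counts[sp, on = c("drug", "norm_pt")][, .(drug, pt, bin, count)]
  out <- counts[grid, on = c("drug", "pt", "bin")]
  out[is.na(count), count := 0L]
  setorder(out, drug, pt, bin)
  out[]
}
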