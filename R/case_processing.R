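# Case-level processing: deduplication, restriction to primary-suspect target
# drugs with a qualifying indication inside the approval window, and
# time-to-onset computation.

#' Deduplicate case versions
#'
#' A spontaneous report may be submitted several times; all versions share a
#' CASEID but carry distinct PRIMARYIDs. Per CASEID the version with the
#' latest FDA reception date (FDA_DT) is retained; among equal FDA_DT the
#' highest PRIMARYID wins. Partial FDA_DT values are ordered by the zero-fill
#' key of [partial_date_key()], so lower-precision dates sort as older. The
#' selection is deterministic and invariant to input row order.
#'
#' @param demo a DEMO data.table with at least `primaryid`, `caseid`,
#'   `fda_dt` columns (character).
#' @return list with `demo` (one row per CASEID), `n_removed` (dropped
#'   versions), and `kept_primaryids`.
#' @export
deduplicate_cases <- function(demo) {
  demo <- as.data.table(demo)
  if (nrow(demo) == 0L) {
    return(list(demo = demo, n_removed = 0L, kept_primaryids = character(0)))
  }
  work <- copy(demo)
  work[, fda_key := partial_date_key(fda_dt)]
  work[, key_ := suppressWarnings(as.numeric(primaryid))]
  work[is.na(key_), key_ := -Inf]
  setorderv(work, c("caseid", "fda_key", "key_"), order = c(1L, -1L, -1L))
  kept <- work[, .SD[1L], by = caseid]
  kept[, c("fda_key", "key_") := NULL]
  setcolorder(kept, names(demo))
  list(demo = kept[],
       n_removed = nrow(demo) - nrow(kept),
       kept_primaryids = kept$primaryid)
}

#' Restrict a case set to a list of PRIMARYIDs
#'
#' Filters every table of a `faers_quarter` (or plain table list) to the given
#' report identifiers, e.g. the survivors of [deduplicate_cases()].
#'
#' @param x `faers_quarter` or named list of FAERS tables.
#' @param primaryids character vector of report identifiers to keep.
#' @return named list of filtered tables.
#' @export
filter_cases <- function(x, primaryids) {
  tables <- if (inherits(x, "faers_quarter")) x$tables else x
  lapply(tables, function(dt) {
    dt <- as.data.table(dt)
    if ("primaryid" %in% names(dt)) dt[primaryid %in% primaryids] else dt
  })
}

#' Assign reports to target drugs
#'
#' A deduplicated report is assigned to target drug D when (i) some drug row
#' with role code PS matches D's synonym set on the normalized DRUGNAME or
#' PROD_AI, (ii) an indication row whose `indi_drug_seq` links to a matching
#' PS row carries an indication term from `indication_terms` (with
#' `indication_mode = "anywhere"`, any indication row of the report
#' qualifies), and (iii) the report's FDA_DT is on or after D's approval date.
#' Matching is exact on normalized strings; no substring matching. A report
#' whose PS drugs match two different target drugs is counted as ambiguous
#' and excluded.
#'
#' @param tables named list of FAERS tables (after deduplication), needing
#'   `demo`, `drug`, `indi`.
#' @param dictionary a `drug_dictionary` (see [load_drug_dictionary()]).
#' @param indication_terms character vector of qualifying indication PTs;
#'   default [mg_indication_terms()].
#' @param indication_mode `"linked"` (default) requires the indication to be
#'   attached to the matching PS drug via its sequence number; `"anywhere"`
#'   accepts an indication anywhere in the report.
#' @return list with `assignments` (data.table `primaryid`, `drug`,
#'   `drug_seq` of the matched PS rows), `n_ambiguous`, and `flow`, a
#'   flow-report data.table of counts at each filter stage.
#' @export
select_target_cases <- function(tables, dictionary,
                                indication_terms = mg_indication_terms(),
                                indication_mode = c("linked", "anywhere")) {
  indication_mode <- match.arg(indication_mode)
  if (length(indication_terms) == 0L) sk_stop("indication term set is empty")
  demo <- as.data.table(tables$demo)
  drug <- as.data.table(tables$drug)
  indi <- as.data.table(tables$indi)

  syn_map <- rbindlist(lapply(names(dictionary), function(nm) {
    data.table(match_drug = nm, norm_name = dictionary[[nm]]$synonyms)
  }))
  appr <- stats::setNames(vapply(dictionary, `[[`, numeric(1), "approval_key"),
                          names(dictionary))

  ps <- drug[normalize_text(role_cod) == "ps"]
  ps[, norm_name := normalize_text(drugname)]
  ps[, norm_ai := if ("prod_ai" %in% names(ps)) normalize_text(prod_ai) else ""]
  hit_name <- syn_map[ps, on = "norm_name", nomatch = NULL]
  ps2 <- copy(ps)[, norm_name := norm_ai]
  hit_ai <- syn_map[ps2[nzchar(norm_name)], on = "norm_name", nomatch = NULL]
  hits <- unique(rbindlist(list(hit_name, hit_ai), fill = TRUE),
                 by = c("primaryid", "drug_seq", "match_drug"))

  n_dedup <- nrow(demo)
  n_ps_match <- uniqueN(hits$primaryid)

  ind <- copy(indi)
  ind[, norm_pt := normalize_text(indi_pt)]
  terms <- normalize_text(indication_terms)
  ind <- ind[norm_pt %in% terms]
  if (indication_mode == "linked") {
    qual <- hits[ind, on = c(primaryid = "primaryid", drug_seq = "indi_drug_seq"),
                 nomatch = NULL]
  } else {
    qual <- hits[primaryid %in% unique(ind$primaryid)]
  }
  qual <- unique(qual, by = c("primaryid", "drug_seq", "match_drug"))
  n_indi <- uniqueN(qual$primaryid)

  fda <- demo[, .(primaryid, fda_key = partial_date_key(fda_dt))]
  qual <- fda[qual, on = "primaryid"]
  qual <- qual[fda_key >= appr[match_drug]]
  n_window <- uniqueN(qual$primaryid)

  per_report <- qual[, .(n_drugs = uniqueN(match_drug)), by = primaryid]
  ambiguous <- per_report[n_drugs > 1L, primaryid]
  assignments <- qual[!primaryid %in% ambiguous,
                      .(primaryid, drug = match_drug, drug_seq)]
  assignments <- unique(assignments, by = c("primaryid", "drug", "drug_seq"))

  flow <- rbindlist(list(
    data.table(stage = "deduplicated_reports", drug = "all", count = n_dedup),
    data.table(stage = "ps_match", drug = "all", count = n_ps_match),
    data.table(stage = "ps_and_indication", drug = "all", count = n_indi),
    data.table(stage = "within_approval_window", drug = "all", count = n_window),
    data.table(stage = "ambiguous_excluded", drug = "all",
               count = length(ambiguous)),
    assignments[, .(stage = "assigned", count = uniqueN(primaryid)), by = drug][,
                .(stage, drug, count)]
  ), use.names = TRUE)

  list(assignments = assignments[], n_ambiguous = length(ambiguous), flow = flow)
}

#' Time to onset in days
#'
#' Days from therapy start to event date. Defined only when both tokens have
#' day precision; the same-day case maps to 1 (the printed minimum of onset
#' tables), negative differences are treated as data errors and return `NA`.
#'
#' @param start,event character vectors of raw date tokens (recycled to a
#'   common length).
#' @return integer vector; `NA` where undefined.
#' @export
#' @examples
#' onset_days("20240110", "20240110")  # 1
#' onset_days("20240101", "20240131")  # 30
onset_days <- function(start, event) {
  n <- max(length(start), length(event))
  s <- partial_date_as_date(rep_len(as.character(start), n))
  e <- partial_date_as_date(rep_len(as.character(event), n))
  d <- as.integer(e - s)
  d[!is.na(d) & d == 0L] <- 1L
  d[!is.na(d) & d < 0L] <- NA_integer_
  d
}

#' Per-report onset for assigned cases
#'
#' For each assigned report, the therapy anchor is the earliest day-precision
#' START_DT among the THER rows of the matched PS drug(s); the event anchor is
#' the report's EVENT_DT. Onset is then [onset_days()] of the two.
#'
#' @param assignments assignment table from [select_target_cases()].
#' @param tables named list of FAERS tables with `demo` and `ther`.
#' @return data.table `primaryid`, `drug`, `onset` (integer days, `NA` when
#'   either anchor lacks day precision).
#' @export
case_onset_days <- function(assignments, tables) {
  demo <- as.data.table(tables$demo)
  ther <- as.data.table(tables$ther)
  out <- unique(as.data.table(assignments)[, .(primaryid, drug)])
  th <- ther[as.data.table(assignments), on = c("primaryid", "drug_seq"),
             nomatch = NULL]
  if (nrow(th) > 0L) {
    th[, start_date := partial_date_as_date(start_dt)]
    starts <- th[!is.na(start_date),
                 .(start_date = min(start_date)), by = .(primaryid, drug)]
  } else {
    starts <- data.table(primaryid = character(0), drug = character(0),
                         start_date = as.Date(character(0)))
  }
  ev <- demo[, .(primaryid, event_date = partial_date_as_date(event_dt))]
  out <- starts[out, on = c("primaryid", "drug")]
  out <- ev[out, on = "primaryid"]
  d <- as.integer(out$event_date - out$start_date)
  d[!is.na(d) & d == 0L] <- 1L
  d[!is.na(d) & d < 0L] <- NA_integer_
  out[, onset := d]
  out[, .(primaryid, drug, onset)]
}

# non-standard-eval column created inside case_onset_days
utils::globalVariables(c("start_date", "event_date"))
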