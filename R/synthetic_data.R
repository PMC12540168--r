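# Seeded generator of FAERS-like quarterly tables with known ground truth.
#
# The generator emulates the statistical structure the signal-detection
# pipeline assumes: multi-table case records keyed by PRIMARYID/CASEID,
# duplicate case versions with a later FDA_DT, primary-suspect drug rows
# matched against a generic+brand dictionary, indication rows linked to the
# suspect drug, event PTs drawn per report as independent Bernoulli trials
# whose probability is a baseline times a planted relative risk, heavy
# demographic missingness, and therapy/event dates realizing a chosen
# time-to-onset distribution. Every source of randomness flows from a single
# seed through per-stage derived streams, so outputs are byte-identical for
# a fixed seed and adding a field to one stage does not shift the draws of
# another.

# Report-level PT occurrence model: each vocabulary PT occurs independently
# with probability baseline * rr(drug, pt). A report whose Bernoulli draws
# all come up empty receives the fallback PT (the disease-progression term
# "Myasthenia gravis", itself common in spontaneous reports), so every
# report carries at least one reaction; the fallback PT's realized frequency
# therefore exceeds its baseline and is excluded from moment checks.
SIM_FALLBACK_PT <- "Myasthenia gravis"

sim_pt_vocabulary <- function(n_pts = 120) {
  named <- c(
    "Fatigue", "Headache", "Arthralgia", "Nausea", "Diarrhoea", "Myalgia",
    "Asthenia", "Dyspnoea", "Drug ineffective", "Pyrexia", "Dizziness",
    "Vomiting", "Rash", "Pain", "Injection site pain", "Urinary tract infection",
    "Nasopharyngitis", "Muscular weakness", "Pneumonia", "Insomnia",
    "Pruritus", "Cough", "Back pain", "Malaise", "Fall", "Anxiety",
    "Myasthenia gravis crisis", "Somnolence", "Alopecia", "Hypertension",
    "Herpes zoster", "Condition aggravated", "Influenza", "Oedema peripheral",
    "Chest pain", "Palpitations", "Weight decreased", "Weight increased",
    "Dysphagia", "Vision blurred", "Eyelid ptosis", "Gait disturbance",
    "Muscle spasms", "Paraesthesia", "Hypoaesthesia", "Memory impairment",
    "Depression", "Abdominal pain", "Constipation", "Dyspepsia",
    "Decreased appetite", "Dehydration", "Hyperhidrosis", "Night sweats",
    "Infusion site pruritus", "Injection site erythema", "Injection site bruising",
    "Neck pain", "Speech disorder", "Tremor", "Dry mouth", "Dry eye",
    "Tinnitus", "Vertigo", "Meningococcal infection", "Sepsis",
    "COVID-19", "Bronchitis", "Sinusitis", "Cystitis", "Cellulitis",
    "Blood pressure increased", "Heart rate increased", "Atrial fibrillation",
    "Syncope", "Migraine", "Photophobia", "Diplopia", "Dysarthria",
    "Feeling abnormal", "Therapeutic response shortened", "Symptom recurrence",
    "Hypoacusis", "Gastric cancer", "Nephrolithiasis", "Embolic stroke",
    "Peripheral vascular disorder", "Psoriatic arthropathy",
    "Meningitis aseptic", "Dysuria", "Prostatitis", "Angina pectoris",
    "Cardiac failure congestive", "Hepatic failure", "Pulmonary congestion",
    "Arthritis", "Thyroid disorder", "Systemic lupus erythematosus",
    "Vitiligo", "Product dose omission issue", "Therapy interruption"
  )
  extra <- sprintf("Synthetic event %03d", seq_len(max(0, n_pts - length(named))))
  pts <- c(named, extra)[seq_len(n_pts)]
  # geometric decay gives a few very common terms and a long rare tail;
  # the sum (~3) is the mean number of Bernoulli reactions per report
  baseline <- 0.08 * exp(-0.025 * (seq_len(n_pts) - 1))
  vocab <- data.table(pt = pts, baseline = baseline)
  # rare planted-candidate PTs sit at fixed low baselines so that a relative
  # risk of 8 on a drug with a few thousand reports yields a-cells near 40
  vocab[pt == "Gastric cancer", baseline := 0.0010]
  vocab[pt == "Hypoacusis", baseline := 0.0017]
  vocab[pt == "Nephrolithiasis", baseline := 0.0020]
  vocab[pt == "Meningitis aseptic", baseline := 0.0008]
  vocab[pt == "Embolic stroke", baseline := 0.0009]
  vocab <- rbind(vocab, data.table(pt = SIM_FALLBACK_PT, baseline = 0.15))
  vocab
}

#' Simulation configuration
#'
#' Assembles (and validates) the generator's configuration. The defaults are
#' the study conditions of the package's test bed: the five target biologics
#' at the report volumes of their published characteristics table, a
#' background population bringing the window to roughly 5e4 reports, three
#' drug-event pairs planted at relative risk 8 with expected a-cells near 40,
#' a 10% duplicate-version rate, demographic missingness at spontaneous-report
#' levels, and a log-normal time-to-onset with median 25 days.
#'
#' @param seed integer seed driving all randomness.
#' @param n_cases named integer vector of unique case counts per target drug.
#' @param n_background unique background cases in the window.
#' @param vocabulary data.table `pt, baseline` of event terms and their
#'   per-report occurrence probabilities.
#' @param planted_effects data.table `drug, pt, rr` of planted relative
#'   risks; every `pt` must exist in the vocabulary.
#' @param duplicate_fraction fraction of cases re-emitted as a second version
#'   (new PRIMARYID, later FDA_DT); must be in [0, 0.5].
#' @param missingness named list of missingness rates for `sex`, `age`,
#'   `weight`, `occupation`, `country`.
#' @param onset_fraction fraction of reports given day-precision therapy
#'   start and event dates (the rest have no computable onset).
#' @param date_degrade_fraction fraction of emitted event dates degraded to
#'   month precision, exercising partial-date handling.
#' @param onset_meanlog,onset_sdlog log-normal parameters of onset days.
#' @param serious_prob probability that a report carries outcome codes.
#' @param indication_fraction fraction of target-drug reports whose linked
#'   indication is an MG term (the rest get another indication and are
#'   excluded by the selection stage).
#' @param window_start,window_end first/last FDA receipt date (`YYYYMMDD`).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_cases = c(eculizumab = 5276L, ravulizumab = 3031L,
                                   zilucoplan = 221L, efgartigimod = 2446L,
                                   rozanolixizumab = 370L),
                       n_background = 39000L,
                       vocabulary = sim_pt_vocabulary(),
                       planted_effects = data.table(
                         drug = c("eculizumab", "ravulizumab", "efgartigimod"),
                         pt = c("Gastric cancer", "Hypoacusis", "Nephrolithiasis"),
                         rr = c(8, 8, 8)),
                       duplicate_fraction = 0.10,
                       missingness = list(sex = 0.15, age = 0.75, weight = 0.85,
                                          occupation = 0.10, country = 0.05),
                       onset_fraction = 0.15,
                       date_degrade_fraction = 0.05,
                       onset_meanlog = log(25), onset_sdlog = 1.4,
                       serious_prob = 0.55,
                       indication_fraction = 0.95,
                       window_start = "20171001", window_end = "20250331") {
  vocabulary <- as.data.table(vocabulary)
  planted_effects <- as.data.table(planted_effects)
  stopifnot(all(vocabulary$baseline >= 0 & vocabulary$baseline <= 1),
            all(planted_effects$rr > 0),
            duplicate_fraction >= 0, duplicate_fraction <= 0.5)
  missing_pts <- setdiff(planted_effects$pt, vocabulary$pt)
  if (length(missing_pts) > 0L) {
    sk_stop("planted PT(s) absent from vocabulary: ",
            paste(missing_pts, collapse = ", "))
  }
  structure(list(
    seed = as.integer(seed), n_cases = n_cases, n_background = n_background,
    vocabulary = vocabulary, planted_effects = planted_effects,
    duplicate_fraction = duplicate_fraction, missingness = missingness,
    onset_fraction = onset_fraction,
    date_degrade_fraction = date_degrade_fraction,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    serious_prob = serious_prob, indication_fraction = indication_fraction,
    window_start = window_start, window_end = window_end
  ), class = "sim_config")
}

SIM_DRUG_NAMES <- list(
  eculizumab = c("ECULIZUMAB", "SOLIRIS"),
  ravulizumab = c("RAVULIZUMAB", "ULTOMIRIS"),
  zilucoplan = c("ZILUCOPLAN", "ZILBRYSQ"),
  efgartigimod = c("EFGARTIGIMOD", "VYVGART"),
  rozanolixizumab = c("ROZANOLIXIZUMAB", "RYSTIGGO")
)

SIM_BACKGROUND_DRUGS <- c(
  "PYRIDOSTIGMINE BROMIDE", "PREDNISONE", "AZATHIOPRINE", "METFORMIN",
  "ATORVASTATIN", "LISINOPRIL", "ADALIMUMAB", "IBUPROFEN", "OMEPRAZOLE",
  "LEVOTHYROXINE", "MYCOPHENOLATE MOFETIL", "RITUXIMAB")

SIM_OTHER_INDICATIONS <- c(
  "Paroxysmal nocturnal haemoglobinuria", "Atypical haemolytic uraemic syndrome",
  "Neuromyelitis optica spectrum disorder", "Immune thrombocytopenia",
  "Rheumatoid arthritis", "Hypertension", "Type 2 diabetes mellitus",
  "Hypothyroidism", "Gastrooesophageal reflux disease", "Pain")

SIM_MG_APPROVALS <- c(eculizumab = "20171023", ravulizumab = "20220427",
                      zilucoplan = "20231017", efgartigimod = "20211217",
                      rozanolixizumab = "20230626")

sample_outcome_codes <- function(n) {
  probs <- c(HO = 0.45, DE = 0.06, LT = 0.03, DS = 0.005, CA = 0.001,
             RI = 0.003, OT = 0.65)
  draws <- lapply(names(probs), function(code) {
    which(runif(n) < probs[[code]])
  })
  names(draws) <- names(probs)
  out <- rbindlist(lapply(names(draws), function(code) {
    data.table(case = draws[[code]], outc_cod = code)
  }))
  none <- setdiff(seq_len(n), unique(out$case))
  if (length(none) > 0L) out <- rbind(out, data.table(case = none, outc_cod = "OT"))
  out
}

#' Generate a synthetic FAERS-like report window
#'
#' Produces the seven quarterly-format tables plus a ground-truth record, per
#' the model described in [sim_config()]. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return object of class `faers_sim`: list with `tables` (the seven FAERS
#'   tables, all-character, ready for [write_faers_quarter()]), and
#'   `ground_truth`: `planted` (the planted effects), `n_unique_cases`,
#'   `n_report_versions`, and `onset` (data.table `primaryid, drug,
#'   onset_days_true, day_precision`).
#' @export
simulate_faers <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 8L)

  drugs <- c(names(config$n_cases), "background")
  n_per <- c(config$n_cases, background = config$n_background)
  n_total <- sum(n_per)
  case_drug <- rep(drugs, times = n_per)
  caseid <- sprintf("%d", 100000000L + seq_len(n_total))
  primaryid <- paste0(caseid, "1")

  win_start <- as.Date(config$window_start, "%Y%m%d")
  win_end <- as.Date(config$window_end, "%Y%m%d")

  ## --- dates -------------------------------------------------------------
  set.seed(stage_seed[1])
  start_floor <- rep(win_start, n_total)
  for (dg in names(SIM_MG_APPROVALS)) {
    if (dg %in% drugs) {
      appr <- as.Date(SIM_MG_APPROVALS[[dg]], "%Y%m%d")
      start_floor[case_drug == dg] <- max(appr, win_start)
    }
  }
  span <- as.integer(win_end - start_floor)
  fda_date <- start_floor + floor(runif(n_total) * (span + 1L))

  has_onset <- runif(n_total) < config$onset_fraction
  onset_true <- pmax(1L, as.integer(round(
    rlnorm(n_total, config$onset_meanlog, config$onset_sdlog))))
  delay <- as.integer(floor(runif(n_total) * 31))
  start_date <- fda_date - onset_true - delay
  event_date <- start_date + onset_true
  degrade <- has_onset & runif(n_total) < config$date_degrade_fraction
  event_tok <- ifelse(has_onset,
                      ifelse(degrade, format(event_date, "%Y%m"),
                             format(event_date, "%Y%m%d")), "")
  start_tok <- ifelse(has_onset, format(start_date, "%Y%m%d"), "")

  ## --- demographics ------------------------------------------------------
  set.seed(stage_seed[2])
  sex <- ifelse(runif(n_total) < 0.55, "F", "M")
  sex[runif(n_total) < config$missingness$sex] <- ""
  age <- round(pmin(pmax(rnorm(n_total, 60.2, 17.6), 1), 100))
  age_tok <- ifelse(runif(n_total) < config$missingness$age, "", as.character(age))
  age_cod <- ifelse(nzchar(age_tok), "YR", "")
  wt <- round(pmin(pmax(rnorm(n_total, 88, 30), 25), 250), 1)
  wt_tok <- ifelse(runif(n_total) < config$missingness$weight, "", as.character(wt))
  wt_cod <- ifelse(nzchar(wt_tok), "KG", "")
  occ_pool <- c("CN", "MD", "HP", "PH", "LW", "OT")
  occ <- sample(occ_pool, n_total, replace = TRUE,
                prob = c(0.65, 0.12, 0.12, 0.03, 0.002, 0.078))
  occ[runif(n_total) < config$missingness$occupation] <- ""
  ctry <- sample(c("US", "JP", "DE", "CA", "FR", "GB"), n_total, replace = TRUE,
                 prob = c(0.85, 0.05, 0.02, 0.02, 0.02, 0.04))
  ctry[runif(n_total) < config$missingness$country] <- ""

  ## --- reactions ---------------------------------------------------------
  set.seed(stage_seed[3])
  vocab <- config$vocabulary
  planted <- config$planted_effects
  pair_ids <- vector("list", length(drugs) * nrow(vocab))
  pair_pts <- vector("list", length(drugs) * nrow(vocab))
  slot <- 0L
  idx_by_drug <- split(seq_len(n_total), case_drug)
  for (dg in drugs) {
    ids <- idx_by_drug[[dg]]
    rrs <- rep(1, nrow(vocab))
    pe <- planted[drug == dg]
    if (nrow(pe) > 0L) rrs[match(pe$pt, vocab$pt)] <- pe$rr
    probs <- pmin(vocab$baseline * rrs, 0.95)
    for (j in seq_len(nrow(vocab))) {
      n_with <- rbinom(1L, length(ids), probs[j])
      if (n_with > 0L) {
        slot <- slot + 1L
        pair_ids[[slot]] <- sample(ids, n_with)
        pair_pts[[slot]] <- rep(vocab$pt[j], n_with)
      }
    }
  }
  pair_case <- unlist(pair_ids[seq_len(slot)], use.names = FALSE)
  pair_pt <- unlist(pair_pts[seq_len(slot)], use.names = FALSE)
  empty <- setdiff(seq_len(n_total), unique(pair_case))
  if (length(empty) > 0L) {
    pair_case <- c(pair_case, empty)
    pair_pt <- c(pair_pt, rep(SIM_FALLBACK_PT, length(empty)))
  }
  ord <- order(pair_case, pair_pt)
  reac <- data.table(primaryid = primaryid[pair_case[ord]],
                     caseid = caseid[pair_case[ord]], pt = pair_pt[ord])

  ## --- drug & indication tables ------------------------------------------
  set.seed(stage_seed[4])
  ps_name <- character(n_total)
  for (dg in names(SIM_DRUG_NAMES)) {
    ids <- idx_by_drug[[dg]]
    if (length(ids) > 0L) {
      ps_name[ids] <- sample(SIM_DRUG_NAMES[[dg]], length(ids), replace = TRUE)
    }
  }
  bg_ids <- idx_by_drug[["background"]]
  ps_name[bg_ids] <- sample(SIM_BACKGROUND_DRUGS, length(bg_ids), replace = TRUE)
  prod_ai <- ifelse(case_drug == "background", ps_name, toupper(case_drug))

  is_target <- case_drug != "background"
  mg_terms <- mg_indication_terms()
  indi_pt <- character(n_total)
  mg_pick <- sample(mg_terms, n_total, replace = TRUE,
                    prob = c(0.80, 0.10, 0.03, 0.07))
  other_pick <- sample(SIM_OTHER_INDICATIONS, n_total, replace = TRUE)
  use_mg <- is_target & runif(n_total) < config$indication_fraction
  indi_pt[use_mg] <- mg_pick[use_mg]
  indi_pt[!use_mg] <- other_pick[!use_mg]
  # background reports keep a realistic share of MG indications too
  bg_mg <- bg_ids[runif(length(bg_ids)) < 0.02]
  indi_pt[bg_mg] <- mg_pick[bg_mg]

  n_conco <- sample(0:2, n_total, replace = TRUE, prob = c(0.5, 0.3, 0.2))
  conco_rows <- data.table(
    case = rep(seq_len(n_total), n_conco),
    seq = unlist(lapply(n_conco[n_conco > 0L], function(k) 1L + seq_len(k)),
                 use.names = FALSE))
  conco_rows[, drugname := sample(SIM_BACKGROUND_DRUGS, .N, replace = TRUE)]

  drug_tab <- rbind(
    data.table(case = seq_len(n_total), seq = 1L, role_cod = "PS",
               drugname = ps_name, prod_ai = prod_ai),
    data.table(case = conco_rows$case, seq = conco_rows$seq, role_cod = "C",
               drugname = conco_rows$drugname, prod_ai = conco_rows$drugname))
  setorder(drug_tab, case, seq)
  drug <- drug_tab[, .(primaryid = primaryid[case], caseid = caseid[case],
                       drug_seq = as.character(seq), role_cod, drugname, prod_ai)]
  indi <- data.table(primaryid = primaryid, caseid = caseid,
                     indi_drug_seq = "1", indi_pt = indi_pt)

  ## --- outcomes & report sources -----------------------------------------
  set.seed(stage_seed[5])
  serious <- runif(n_total) < config$serious_prob
  ser_idx <- which(serious)
  oc <- sample_outcome_codes(length(ser_idx))
  outc <- data.table(primaryid = primaryid[ser_idx[oc$case]],
                     caseid = caseid[ser_idx[oc$case]], outc_cod = oc$outc_cod)
  setorder(outc, primaryid, outc_cod)
  rpsr <- data.table(primaryid = primaryid, caseid = caseid,
                     rpsr_cod = sample(c("CSM", "HP", "FGN", "OTH"), n_total,
                                       replace = TRUE, prob = c(0.6, 0.25, 0.1, 0.05)))

  demo <- data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = format(fda_date, "%Y%m%d"), event_dt = event_tok,
    age = age_tok, age_cod = age_cod, sex = sex, wt = wt_tok, wt_cod = wt_cod,
    occp_cod = occ, reporter_country = ctry)
  ther <- data.table(primaryid = primaryid[has_onset], caseid = caseid[has_onset],
                     drug_seq = "1", start_dt = start_tok[has_onset],
                     end_dt = "")

  ## --- duplicate case versions -------------------------------------------
  set.seed(stage_seed[6])
  n_dup <- floor(config$duplicate_fraction * n_total)
  tables <- list(demo = demo, drug = drug, reac = reac, indi = indi,
                 ther = ther, outc = outc, rpsr = rpsr)
  if (n_dup > 0L) {
    dup_case <- sort(sample(seq_len(n_total), n_dup))
    dup_pid_old <- primaryid[dup_case]
    dup_pid_new <- paste0(caseid[dup_case], "2")
    dup_fda <- format(fda_date[dup_case] + sample(1:90, n_dup, replace = TRUE),
                      "%Y%m%d")
    remap <- stats::setNames(dup_pid_new, dup_pid_old)
    new_fda <- stats::setNames(dup_fda, dup_pid_new)
    for (tb in names(tables)) {
      dt <- tables[[tb]]
      cp <- dt[primaryid %in% dup_pid_old]
      if (nrow(cp) > 0L) {
        cp[, primaryid := unname(remap[primaryid])]
        if (tb == "demo") cp[, fda_dt := unname(new_fda[primaryid])]
        tables[[tb]] <- rbind(dt, cp)
      }
    }
    for (tb in names(tables)) setorderv(tables[[tb]], c("caseid", "primaryid"))
  }

  onset_truth <- data.table(
    primaryid = primaryid, drug = case_drug,
    onset_days_true = ifelse(has_onset, onset_true, NA_integer_),
    day_precision = has_onset & !degrade)

  structure(list(
    tables = tables,
    ground_truth = list(planted = copy(config$planted_effects),
                        n_unique_cases = n_total,
                        n_report_versions = nrow(tables$demo),
                        onset = onset_truth),
    config = config
  ), class = "faers_sim")
}

#' Write a simulated window to disk
#'
#' Writes the seven '$'-delimited FAERS-style files plus `ground_truth.csv`
#' (the planted effects and case counts).
#'
#' @param sim a [simulate_faers()] result.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_faers_sim <- function(sim, dir) {
  paths <- write_faers_quarter(sim$tables, dir)
  gt <- copy(sim$ground_truth$planted)
  gt[, `:=`(n_unique_cases = sim$ground_truth$n_unique_cases,
            n_report_versions = sim$ground_truth$n_report_versions)]
  gt_path <- file.path(dir, "ground_truth.csv")
  fwrite(gt, gt_path)
  invisible(c(paths, gt_path))
}

utils::globalVariables(c("case", "seq", "day_precision"))

#' Generate a network-toxicology fixture with planted structure
#'
#' Builds a synthetic gene universe, a study set, a PPI edge list in which
#' the planted hubs receive the top degrees by construction (each hub is
#' wired to most of the study set, non-hub pairs connect sparsely), and a
#' GMT collection containing one term fully contained in the study set
#' (maximal enrichment at its size) and one random term, plus random filler
#' terms.
#'
#' @param seed integer seed.
#' @param n_genes universe size.
#' @param n_study study-set size (includes the hubs).
#' @param planted_hubs gene symbols to plant as hubs (must fit in the study
#'   set).
#' @param n_terms total GMT terms (>= 2).
#' @param dir optional directory: writes `universe.txt`, `study.txt`,
#'   `edges.tsv`, `sets.gmt` when given.
#' @return list `universe`, `study`, `edges` (data.table
#'   `gene_a, gene_b, score`), `gmt` (named list; the planted term is
#'   `CONTAINED_TERM`, the random one `RANDOM_TERM`).
#' @export
generate_network_fixture <- function(seed = 1L, n_genes = 200L, n_study = 30L,
                                     planted_hubs = c("C5", "C3", "ALB"),
                                     n_terms = 6L, dir = NULL) {
  stopifnot(length(planted_hubs) < n_study, n_terms >= 2L)
  set.seed(seed)
  universe <- unique(c(toupper(planted_hubs),
                       sprintf("GENE%04d", seq_len(n_genes))))[seq_len(n_genes)]
  hubs <- toupper(planted_hubs)
  study <- c(hubs, sample(setdiff(universe, hubs), n_study - length(hubs)))

  non_hub <- setdiff(study, hubs)
  hub_edges <- rbindlist(lapply(hubs, function(h) {
    partners <- non_hub[runif(length(non_hub)) < 0.85]
    if (length(partners) == 0L) partners <- non_hub[1L]
    data.table(gene_a = h, gene_b = partners)
  }))
  pairs <- t(utils::combn(non_hub, 2L))
  keep <- runif(nrow(pairs)) < 0.06
  sparse_edges <- data.table(gene_a = pairs[keep, 1L], gene_b = pairs[keep, 2L])
  edges <- rbind(hub_edges, sparse_edges)
  ga <- edges$gene_a; gb <- edges$gene_b
  edges[, `:=`(gene_a = pmin(ga, gb), gene_b = pmax(ga, gb))]
  edges <- unique(edges, by = c("gene_a", "gene_b"))
  edges[, score := round(runif(.N, 0.4, 1), 3)]

  gmt <- list(
    CONTAINED_TERM = sample(study, min(8L, n_study)),
    RANDOM_TERM = sample(universe, 20L)
  )
  if (n_terms > 2L) {
    for (i in seq_len(n_terms - 2L)) {
      gmt[[sprintf("FILLER_TERM_%02d", i)]] <-
        sample(universe, sample(10:40, 1L))
    }
  }

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(universe, file.path(dir, "universe.txt"))
    writeLines(study, file.path(dir, "study.txt"))
    fwrite(edges, file.path(dir, "edges.tsv"), sep = "\t")
    gmt_lines <- vapply(names(gmt), function(tm) {
      paste(c(tm, "synthetic fixture term", gmt[[tm]]), collapse = "\t")
    }, character(1))
    writeLines(gmt_lines, file.path(dir, "sets.gmt"))
  }
  list(universe = universe, study = study, edges = edges[], gmt = gmt)
}
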