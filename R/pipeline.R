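# Config-driven orchestration of the full analysis: load (or simulate) a
# report window, deduplicate, select target cases, write descriptive and
# signal tables, and optionally run the network-toxicology stage. Every run
# writes a manifest (config hash, seed, versions) so outputs are
# reproducible; all tables are CSV with fixed column order and floats at six
# significant digits.

#' Pipeline configuration
#'
#' Builds a validated pipeline configuration from a YAML file or an R list.
#' Recognized keys (all optional unless noted): `input` (directory of FAERS
#' files; omit to simulate), `simulate` (logical; defaults to `TRUE` when no
#' input), `seed`, `dictionary` (YAML path; default: the built-in MG
#' dictionary), `indication_terms`, `indication_mode`, `comparator`
#' (`window`/`targets`), `chi2` (`pearson`/`yates`), `zero_cell`
#' (`suppress`/`haldane`), `unit` (`report`/`pair`), `stratify` (subset of
#' `sex`, `occupation`), `soc_map` (TSV path), `network` (list with paths
#' `drug_targets`, `soc_targets`, `edges`, `gmt`, optional `universe`),
#' `sim` (named list of [sim_config()] overrides for simulated runs),
#' `out_dir` (required).
#'
#' @param x path to a YAML file, or a named list.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1L) yaml::read_yaml(x) else x
  defaults <- list(seed = 1L, simulate = is.null(cfg$input),
                   indication_terms = mg_indication_terms(),
                   indication_mode = "linked", comparator = "window",
                   chi2 = "pearson", zero_cell = "suppress", unit = "report",
                   stratify = character(0))
  cfg <- modifyList(defaults, cfg)
  if (is.null(cfg$out_dir)) sk_stop("pipeline config needs 'out_dir'")
  for (key in c("input", "dictionary", "soc_map")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      sk_stop("config path does not exist: ", key, " = ", cfg[[key]])
    }
  }
  for (key in names(cfg$network)) {
    if (!file.exists(cfg$network[[key]])) {
      sk_stop("network input does not exist: ", cfg$network[[key]])
    }
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

write_csv6 <- function(dt, path) {
  dt <- copy(as.data.table(dt))
  for (col in names(dt)) {
    if (is.double(dt[[col]])) dt[, (col) := signif(get(col), 6)]
  }
  fwrite(dt, path)
  path
}

#' Run the full pipeline
#'
#' Executes every stage behind a configuration and writes its artifact
#' bundle into `out_dir`: `flow_report.csv`, `load_report.csv`,
#' `table1_categorical.csv`, `table1_continuous.csv`, `trend.csv`,
#' `signals.csv`, `top_counts.csv`, `top_ror.csv`, `venn.csv`,
#' `onset_profile.csv`, `soc_rollup.csv`, per-stratum subgroup tables, the
#' network outputs (`venn_genes.csv`, `hubs.csv`, `enrichment.csv`) when
#' configured, and `manifest.yaml`. Rerunning an identical configuration
#' reproduces identical bytes.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param quiet suppress stage logging.
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  say <- function(...) if (!quiet) message("[signalkit] ", ...)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## stage: load ------------------------------------------------------------
  if (!is.null(cfg$input)) {
    say("loading FAERS tables from ", cfg$input)
    quarter <- read_faers_quarter(cfg$input, quarter = cfg$quarter %||% NA)
    tables <- quarter$tables
    load_report <- quarter$load_report
  } else {
    say("simulating report window (seed ", cfg$seed, ")")
    sim_args <- c(list(seed = cfg$seed), cfg$sim)
    if (!is.null(sim_args$n_cases)) sim_args$n_cases <- unlist(sim_args$n_cases)
    sim <- simulate_faers(do.call(sim_config, sim_args))
    tables <- sim$tables
    load_report <- data.table(table = names(tables), file = "simulated",
                              n_records = vapply(tables, nrow, integer(1)),
                              n_malformed = 0L, n_undecodable = 0L, n_orphan = 0L)
  }
  write_csv6(load_report, file.path(cfg$out_dir, "load_report.csv"))

  ## stage: dedup + selection ------------------------------------------------
  dd <- deduplicate_cases(tables$demo)
  say("deduplicated: ", nrow(dd$demo), " cases (", dd$n_removed, " versions removed)")
  tables <- filter_cases(tables, dd$kept_primaryids)
  dict <- if (is.null(cfg$dictionary)) mg_drug_dictionary() else
    load_drug_dictionary(cfg$dictionary)
  sel <- select_target_cases(tables, dict,
                             indication_terms = cfg$indication_terms,
                             indication_mode = cfg$indication_mode)
  flow <- rbind(data.table(stage = "report_versions_loaded", drug = "all",
                           count = nrow(as.data.table(tables$demo)) + dd$n_removed),
                sel$flow)
  write_csv6(flow, file.path(cfg$out_dir, "flow_report.csv"))
  if (nrow(sel$assignments) == 0L) {
    sk_warn("no target cases after filtering; writing empty outputs")
  }

  ## stage: descriptives ------------------------------------------------------
  onset <- case_onset_days(sel$assignments, tables)
  chars <- characteristics_table(sel$assignments, tables, onset = onset)
  write_csv6(chars$categorical, file.path(cfg$out_dir, "table1_categorical.csv"))
  write_csv6(chars$continuous, file.path(cfg$out_dir, "table1_continuous.csv"))
  asg <- unique(as.data.table(sel$assignments)[, .(primaryid, drug)])
  demo <- as.data.table(tables$demo)
  trend <- rbindlist(c(
    list(data.table(drug = character(0), period = character(0), count = integer(0))),
    lapply(sort(unique(asg$drug)), function(dg) {
      tc <- trend_counts(demo[primaryid %in% asg[drug == dg, primaryid], fda_dt])
      cbind(data.table(drug = dg), tc)
    })))
  write_csv6(trend, file.path(cfg$out_dir, "trend.csv"))

  ## stage: signal detection --------------------------------------------------
  signals <- data.table(
    drug = character(0), pt = character(0), a = integer(0), b = integer(0),
    c_ = integer(0), d = integer(0), ror = numeric(0), ror_ci_low = numeric(0),
    ror_ci_high = numeric(0), prr = numeric(0), chi2 = numeric(0),
    ic = numeric(0), ic025 = numeric(0), flag_ror = logical(0),
    flag_mhra = logical(0), flag_bcpnn = logical(0), flag_all3 = logical(0))
  if (nrow(sel$assignments) > 0L) {
    say("signal detection (comparator = ", cfg$comparator, ")")
    ctabs <- build_contingency_tables(sel$assignments, tables$reac,
                                      universe_ids = demo$primaryid,
                                      comparator = cfg$comparator,
                                      unit = cfg$unit)
    signals <- signal_stats(ctabs, zero_cell = cfg$zero_cell,
                            chi2_correction = cfg$chi2)
  }
  write_csv6(signals, file.path(cfg$out_dir, "signals.csv"))
  if (nrow(signals) > 0L) {
    write_csv6(rank_signals(signals, "count"), file.path(cfg$out_dir, "top_counts.csv"))
    write_csv6(rank_signals(signals, "ror"), file.path(cfg$out_dir, "top_ror.csv"))
    write_csv6(venn_counts(signals), file.path(cfg$out_dir, "venn.csv"))
    pos <- signals[flag_all3 == TRUE, .(drug, pt, reports = a)]
    profile <- pt_onset_profile(pos[, .(drug, pt)], tables$reac, onset)
    write_csv6(profile, file.path(cfg$out_dir, "onset_profile.csv"))
    soc_map <- if (!is.null(cfg$soc_map)) load_soc_map(cfg$soc_map) else
      structure(character(0), class = "soc_map")
    write_csv6(soc_rollup(pos, soc_map), file.path(cfg$out_dir, "soc_rollup.csv"))
    for (st in cfg$stratify) {
      say("stratified rerun by ", st)
      sr <- stratified_signals(sel$assignments, tables, stratum = st,
                               comparator = cfg$comparator, unit = cfg$unit)
      for (sv in names(sr$strata)) {
        if (nrow(sr$strata[[sv]]) > 0L) {
          write_csv6(sr$strata[[sv]],
                     file.path(cfg$out_dir, sprintf("signals_%s_%s.csv", st, sv)))
        }
      }
    }
  }

  ## stage: network toxicology -------------------------------------------------
  network <- NULL
  if (!is.null(cfg$network)) {
    say("network-toxicology stage")
    nw <- cfg$network
    drug_targets <- read_gene_list(nw$drug_targets)
    soc_targets <- read_gene_list(nw$soc_targets)
    inter <- intersect_gene_sets(drug_targets, soc_targets)
    edges <- read_edge_list(nw$edges, min_score = nw$min_score %||% 0.4)
    hubs <- hub_nodes(edges, inter$genes, k = nw$k %||% 5L)
    gmt <- read_gmt(nw$gmt)
    universe <- if (!is.null(nw$universe)) read_gene_list(nw$universe) else NULL
    enr <- enrich_gene_sets(inter$genes, gmt, universe = universe)
    write_csv6(inter$venn, file.path(cfg$out_dir, "venn_genes.csv"))
    write_csv6(hubs, file.path(cfg$out_dir, "hubs.csv"))
    write_csv6(enr, file.path(cfg$out_dir, "enrichment.csv"))
    network <- list(intersection = inter, hubs = hubs, enrichment = enr)
  }

  ## manifest -------------------------------------------------------------------
  cfg_plain <- unclass(cfg)
  cfg_plain$out_dir <- NULL  # hash the analysis config, not where it lands
  cfg_yaml <- yaml::as.yaml(cfg_plain[order(names(cfg_plain))])
  tmp <- tempfile()
  writeLines(cfg_yaml, tmp)
  manifest <- list(config_md5 = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   signalkit_version = as.character(packageVersion("signalkit")),
                   r_version = R.version.string)
  unlink(tmp)
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  say("done; outputs in ", cfg$out_dir)

  invisible(list(tables = tables, selection = sel, onset = onset,
                 characteristics = chars, signals = signals,
                 network = network, flow = flow, manifest = manifest))
}
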