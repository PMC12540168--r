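# In-code fixtures: tiny FAERS-style quarters and auxiliary files, built at
# test time. All builders return paths inside a fresh temp directory.

write_dollar <- function(path, header, lines) {
  writeLines(c(paste(header, collapse = "$"), lines), path)
  path
}

# A minimal, fully well-formed quarter: 3 cases of which two share a CASEID
# (duplicate versions), one eculizumab PS report with an MG indication.
tiny_quarter_dir <- function(dir = tempfile("quarter")) {
  dir.create(dir)
  write_dollar(file.path(dir, "DEMO.txt"),
    c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod", "sex",
      "wt", "wt_cod", "occp_cod", "reporter_country"),
    c("1001$100$20240110$20240105$64$YR$F$80$KG$CN$US",
      "1002$100$20240301$20240105$64$YR$F$80$KG$CN$US",
      "2001$200$20240215$$$$M$$$MD$JP",
      "3001$300$20240220$$55$YR$F$$$HP$US"))
  write_dollar(file.path(dir, "DRUG.txt"),
    c("primaryid", "caseid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    c("1001$100$1$PS$SOLIRIS$ECULIZUMAB",
      "1002$100$1$PS$SOLIRIS$ECULIZUMAB",
      "2001$200$1$PS$VYVGART$EFGARTIGIMOD",
      "2001$200$2$C$PREDNISONE$PREDNISONE",
      "3001$300$1$SS$SOLIRIS$ECULIZUMAB"))
  write_dollar(file.path(dir, "REAC.txt"),
    c("primaryid", "caseid", "pt"),
    c("1001$100$Headache", "1002$100$Headache", "1002$100$Fatigue",
      "2001$200$Nausea", "3001$300$Headache"))
  write_dollar(file.path(dir, "INDI.txt"),
    c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
    c("1001$100$1$Myasthenia gravis", "1002$100$1$Myasthenia gravis",
      "2001$200$1$Myasthenia gravis",
      "3001$300$1$Myasthenia gravis"))
  write_dollar(file.path(dir, "THER.txt"),
    c("primaryid", "caseid", "drug_seq", "start_dt", "end_dt"),
    c("1002$100$1$20240101$", "2001$200$1$20240201$"))
  write_dollar(file.path(dir, "OUTC.txt"),
    c("primaryid", "caseid", "outc_cod"),
    c("1002$100$HO", "2001$200$DE"))
  write_dollar(file.path(dir, "RPSR.txt"),
    c("primaryid", "caseid", "rpsr_cod"),
    c("1001$100$CSM", "1002$100$CSM", "2001$200$HP", "3001$300$HP"))
  dir
}

soc_map_path <- function(rows = c("pt\tsoc",
                                  "Headache\tNervous system disorders",
                                  "Nausea\tGastrointestinal disorders"),
                         dir = tempfile("soc")) {
  dir.create(dir)
  f <- file.path(dir, "soc.tsv")
  writeLines(rows, f)
  f
}

dict_path <- function(yaml_text = NULL, dir = tempfile("dict")) {
  dir.create(dir)
  f <- file.path(dir, "dict.yaml")
  if (is.null(yaml_text)) {
    yaml_text <- paste(
      "eculizumab:",
      "  synonyms: [eculizumab, Soliris]",
      "  approval: \"20171023\"",
      "efgartigimod:",
      "  synonyms: [efgartigimod, Vyvgart]",
      "  approval: \"20211217\"",
      sep = "\n")
  }
  writeLines(yaml_text, f)
  f
}

# demo table builder for dedup tests
demo_rows <- function(primaryid, caseid, fda_dt) {
  data.table::data.table(primaryid = as.character(primaryid),
                         caseid = as.character(caseid),
                         fda_dt = as.character(fda_dt))
}

# a small simulated window shared across tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_faers(sim_config(
        seed = 7L,
        n_cases = c(eculizumab = 1500L, efgartigimod = 900L),
        n_background = 6000L))
    }
    cache
  }
})
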