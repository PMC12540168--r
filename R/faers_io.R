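# FAERS quarterly ASCII reader/writer and auxiliary dictionaries.
#
# The quarterly extracts are '$'-delimited text, one header line then one
# record per line, distributed as seven tables. Mandatory tables are DEMO,
# DRUG and REAC; the remaining four are created empty (with a warning) when
# their file is absent so downstream code can rely on their presence.

FAERS_TABLES <- c("demo", "drug", "reac", "indi", "ther", "outc", "rpsr")

faers_empty_columns <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "wt", "wt_cod", "occp_cod", "reporter_country"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "caseid", "pt"),
  indi = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
  ther = c("primaryid", "caseid", "drug_seq", "start_dt", "end_dt"),
  outc = c("primaryid", "caseid", "outc_cod"),
  rpsr = c("primaryid", "caseid", "rpsr_cod")
)

empty_faers_table <- function(table) {
  cols <- faers_empty_columns[[table]]
  dt <- data.table::setnames(
    data.table::as.data.table(replicate(length(cols), character(0),
                                        simplify = FALSE)), cols)
  dt
}

# Parse one '$'-delimited file. Lines with MORE fields than the header are
# rejected and counted (an embedded '$' would silently shift every later
# column); lines with fewer fields are right-padded with empty strings,
# which also absorbs trailing-delimiter truncation.
read_dollar_file <- function(path) {
  raw <- readLines(path, warn = FALSE)
  n_undecodable <- sum(!validUTF8(raw))
  if (n_undecodable > 0) raw <- iconv(raw, from = "UTF-8", to = "UTF-8", sub = "byte")
  if (length(raw) == 0L) sk_stop("file has no header line: ", path)
  header <- strsplit(raw[1L], "$", fixed = TRUE)[[1L]]
  header <- tolower(trimws(header))
  ncol <- length(header)
  body <- raw[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    dt <- data.table::setnames(
      data.table::as.data.table(replicate(ncol, character(0), simplify = FALSE)),
      header)
    return(list(data = dt, n_malformed = 0L, n_undecodable = n_undecodable))
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf > ncol
  parts <- parts[!bad]
  nf <- nf[!bad]
  if (length(parts) > 0L) {
    pad <- nf < ncol
    if (any(pad)) {
      parts[pad] <- lapply(parts[pad], function(p) c(p, rep("", ncol - length(p))))
    }
    m <- matrix(unlist(parts, use.names = FALSE), ncol = ncol, byrow = TRUE)
    dt <- data.table::setnames(data.table::as.data.table(m), header)
  } else {
    dt <- data.table::setnames(
      data.table::as.data.table(replicate(ncol, character(0), simplify = FALSE)),
      header)
  }
  list(data = dt, n_malformed = sum(bad), n_undecodable = n_undecodable)
}

#' Read one FAERS-style quarterly extract
#'
#' Locates the seven '$'-delimited tables in `path` (files whose names begin
#' with the table name, e.g. `DEMO24Q1.txt` or `demo.txt`, case-insensitive)
#' and parses them into character data.tables with lower-cased column names;
#' field values are stored verbatim. Records in child tables whose PRIMARYID
#' does not appear in DEMO are kept but counted as orphans in the load report.
#'
#' @param path directory containing the quarter's files, or a named list/vector
#'   of file paths with names among `demo, drug, reac, indi, ther, outc, rpsr`.
#' @param quarter quarter label, e.g. `"2024Q1"` (free text, carried through).
#' @return an object of class `faers_quarter`: a list with one data.table per
#'   table, the `quarter` label, and `load_report`, a data.table of per-table
#'   record counts, malformed-line counts (lines with more fields than the
#'   header, rejected), undecodable-byte line counts, and orphan counts.
#' @export
read_faers_quarter <- function(path, quarter = NA_character_) {
  if (is.character(path) && length(path) == 1L && dir.exists(path)) {
    files <- list()
    all_files <- list.files(path, full.names = TRUE)
    for (tb in FAERS_TABLES) {
      hit <- all_files[grepl(paste0("^", tb), tolower(basename(all_files)))]
      if (length(hit) > 1L) sk_stop("multiple files match table '", tb, "' in ", path)
      if (length(hit) == 1L) files[[tb]] <- hit
    }
  } else {
    files <- as.list(path)
    names(files) <- tolower(names(files))
  }
  missing_mand <- setdiff(c("demo", "drug", "reac"), names(files))
  if (length(missing_mand) > 0L) {
    sk_stop("missing mandatory FAERS table(s): ",
            paste(toupper(missing_mand), collapse = ", "))
  }

  tables <- list()
  rep_rows <- list()
  for (tb in FAERS_TABLES) {
    if (!is.null(files[[tb]])) {
      parsed <- read_dollar_file(files[[tb]])
      dt <- parsed$data
      extra <- setdiff(names(dt), faers_empty_columns[[tb]])
      if (length(extra) > 0L) {
        sk_warn("table ", toupper(tb), ": keeping unknown column(s) ",
                paste(extra, collapse = ", "))
      }
      tables[[tb]] <- dt
      rep_rows[[tb]] <- data.table(
        table = tb, file = basename(files[[tb]]), n_records = nrow(dt),
        n_malformed = parsed$n_malformed, n_undecodable = parsed$n_undecodable,
        n_orphan = 0L)
    } else {
      sk_warn("table ", toupper(tb), " absent; using empty table")
      tables[[tb]] <- empty_faers_table(tb)
      rep_rows[[tb]] <- data.table(
        table = tb, file = NA_character_, n_records = 0L,
        n_malformed = 0L, n_undecodable = 0L, n_orphan = 0L)
    }
  }
  report <- rbindlist(rep_rows)

  demo_ids <- unique(tables$demo[[grep("^primaryid$", names(tables$demo), value = TRUE)[1]]])
  for (tb in setdiff(FAERS_TABLES, "demo")) {
    dt <- tables[[tb]]
    if (nrow(dt) > 0L && "primaryid" %in% names(dt)) {
      report[table == tb, n_orphan := sum(!dt$primaryid %in% demo_ids)]
    }
  }

  structure(list(tables = tables, quarter = quarter, load_report = report),
            class = "faers_quarter")
}

#' @export
print.faers_quarter <- function(x, ...) {
  cat("FAERS quarter", x$quarter, "\n")
  print(x$load_report)
  invisible(x)
}

#' Write a FAERS-style quarterly extract
#'
#' Writes each table of a `faers_quarter` (or a plain named list of
#' data.tables) as `<TABLE>.txt` in the '$'-delimited layout read by
#' [read_faers_quarter()].
#'
#' @param x a `faers_quarter` object or named list of tables.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_faers_quarter <- function(x, dir) {
  tables <- if (inherits(x, "faers_quarter")) x$tables else x
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (tb in intersect(FAERS_TABLES, names(tables))) {
    f <- file.path(dir, paste0(toupper(tb), ".txt"))
    fwrite(tables[[tb]], f, sep = "$", quote = FALSE, col.names = TRUE)
    paths <- c(paths, f)
  }
  invisible(paths)
}

#' Load a preferred-term to system-organ-class map
#'
#' Reads a two-column tab-separated file (header `pt`, `soc`, case-insensitive)
#' into a lookup used for SOC rollups. Keys are normalized with
#' [normalize_text()]. Duplicate rows mapping one PT to the same SOC collapse
#' with a warning; a PT mapped to two different SOCs is an error, because each
#' preferred term has exactly one primary SOC.
#'
#' @param path path to the TSV file.
#' @return a named character vector of class `soc_map` (names = normalized PT,
#'   values = SOC strings).
#' @export
load_soc_map <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE, colClasses = "character")
  if (ncol(dt) < 2L) sk_stop("SOC map must have two columns (PT, SOC)")
  setnames(dt, tolower(names(dt)))
  if (!all(c("pt", "soc") %in% names(dt))) {
    setnames(dt, names(dt)[1:2], c("pt", "soc"))
  }
  dt[, norm_pt := normalize_text(pt)]
  dt[, soc := trimws(soc)]
  conf <- dt[, uniqueN(soc), by = norm_pt][V1 > 1L]
  if (nrow(conf) > 0L) {
    sk_stop("conflicting SOC mapping for PT(s): ",
            paste(head(conf$norm_pt, 5L), collapse = ", "))
  }
  if (anyDuplicated(dt$norm_pt)) {
    sk_warn("duplicate consistent PT rows collapsed in SOC map")
    dt <- unique(dt, by = "norm_pt")
  }
  structure(stats::setNames(dt$soc, dt$norm_pt), class = "soc_map")
}

#' Map preferred terms to their primary SOC
#'
#' @param pts character vector of PT strings (any case/spacing).
#' @param soc_map a [load_soc_map()] result.
#' @return character vector of SOC names; PTs absent from the map yield the
#'   sentinel `"UNMAPPED_SOC"`.
#' @export
map_pt_to_soc <- function(pts, soc_map) {
  out <- unname(soc_map[normalize_text(pts)])
  out[is.na(out)] <- "UNMAPPED_SOC"
  out
}

#' Load a target-drug dictionary
#'
#' The dictionary is a YAML file mapping each canonical drug name to its match
#' strings (generic plus brand names) and the approval date from which its
#' reports are counted:
#'
#' ```yaml
#' eculizumab:
#'   synonyms: [eculizumab, Soliris]
#'   approval: "20171023"
#' ```
#'
#' Approval dates must have day precision (`YYYYMMDD` or `YYYY-MM-DD`).
#'
#' @param path path to the YAML dictionary.
#' @return a named list of class `drug_dictionary`; each element has
#'   `synonyms` (normalized match strings) and `approval_key` (numeric
#'   `YYYYMMDD` sort key).
#' @export
load_drug_dictionary <- function(path) {
  raw <- yaml::read_yaml(path)
  if (length(raw) == 0L) sk_stop("empty drug dictionary: ", path)
  out <- list()
  for (nm in names(raw)) {
    syn <- unique(normalize_text(c(nm, unlist(raw[[nm]]$synonyms))))
    syn <- syn[nzchar(syn)]
    if (length(syn) == 0L) sk_stop("drug '", nm, "' has no usable match strings")
    appr <- gsub("-", "", as.character(raw[[nm]]$approval %||% ""))
    pd <- parse_partial_date(appr)
    if (is.na(pd$precision[1]) || pd$precision[1] != "day") {
      sk_stop("drug '", nm, "' needs a day-precision approval date")
    }
    out[[nm]] <- list(synonyms = syn, approval_key = partial_date_key(appr))
  }
  structure(out, class = "drug_dictionary")
}

#' Built-in dictionary for the five myasthenia gravis biologics
#'
#' Canonical names, brand-name synonyms and FDA approval dates (for the MG
#' indication) of the three complement C5 inhibitors (eculizumab, ravulizumab,
#' zilucoplan) and two FcRn inhibitors (efgartigimod, rozanolixizumab).
#'
#' @return a `drug_dictionary` (see [load_drug_dictionary()]).
#' @export
mg_drug_dictionary <- function() {
  load_drug_dictionary(system.file("extdata", "mg_drug_dictionary.yaml",
                                   package = "signalkit", mustWork = TRUE))
}

#' Default myasthenia gravis indication terms
#'
#' The preferred terms accepted as an MG indication when restricting reports.
#' Extend or replace via the `indication_terms` argument of
#' [select_target_cases()].
#'
#' @return character vector of PT strings.
#' @export
mg_indication_terms <- function() {
  c("Myasthenia gravis", "Myasthenia gravis crisis", "Ocular myasthenia",
    "Generalised myasthenia gravis")
}
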