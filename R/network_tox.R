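# Network-toxicology stage: gene-set intersection, PPI hub ranking, and
# hypergeometric over-representation analysis with BH-FDR. All inputs are
# files (gene lists, edge-list TSVs, GMT collections) — typically exports
# from STRING/GeneCards/DAVID or synthetic fixtures — so results are
# reproducible offline.

#' Read a gene list
#'
#' One symbol per line; blank lines and `#` comments are skipped. Symbols are
#' upper-cased and deduplicated.
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated file with two gene columns and an optional confidence score
#' in [0, 1]. Self-loops are dropped (and counted in attribute
#' `n_self_loops`); duplicate edges collapse regardless of orientation. When
#' a score column is present, edges below `min_score` are discarded (0.4 is
#' the conventional "medium confidence" cut).
#'
#' @param path file path (header optional: detected when the first row is
#'   non-numeric in column 3 or matches common header names).
#' @param min_score minimum confidence score to keep, when scores exist.
#' @return data.table `gene_a, gene_b` (upper-case, `gene_a < gene_b`), plus
#'   `score` when present.
#' @export
read_edge_list <- function(path, min_score = 0.4) {
  dt <- fread(path, sep = "\t", header = "auto")
  if (ncol(dt) < 2L) sk_stop("edge list needs at least two columns")
  setnames(dt, names(dt)[1:2], c("gene_a", "gene_b"))
  has_score <- ncol(dt) >= 3L
  if (has_score) {
    setnames(dt, names(dt)[3], "score")
    dt[, score := suppressWarnings(as.numeric(score))]
    dt <- dt[!is.na(score) & score >= min_score]
  }
  dt[, `:=`(gene_a = toupper(trimws(gene_a)), gene_b = toupper(trimws(gene_b)))]
  n_self <- dt[gene_a == gene_b, .N]
  dt <- dt[gene_a != gene_b]
  ga <- dt$gene_a; gb <- dt$gene_b
  dt[, `:=`(gene_a = pmin(ga, gb), gene_b = pmax(ga, gb))]
  keep_cols <- intersect(c("gene_a", "gene_b", "score"), names(dt))
  dt <- unique(dt[, ..keep_cols], by = c("gene_a", "gene_b"))
  data.table::setattr(dt, "n_self_loops", n_self)
  dt[]
}

#' Read a GMT annotation collection
#'
#' Standard gene-matrix-transposed format: per line a term id, a description,
#' then the member genes, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors (upper-cased gene symbols); the
#'   descriptions are kept in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "", character(1))
  sets <- lapply(parts, function(p) unique(toupper(trimws(p[-(1:2)]))))
  names(sets) <- terms
  data.table::setattr(sets, "descriptions", stats::setNames(desc, terms))
  sets
}

#' Intersect two gene sets
#'
#' Returns the common symbols along with the Venn region sizes; an empty
#' intersection is valid (with a warning).
#'
#' @param set_a,set_b character vectors of gene symbols (case-insensitive).
#' @return list `genes` (sorted intersection), `venn` (data.table
#'   `region, size` for `a_only`, `intersection`, `b_only`).
#' @export
intersect_gene_sets <- function(set_a, set_b) {
  a <- unique(toupper(set_a)); b <- unique(toupper(set_b))
  common <- sort(intersect(a, b))
  if (length(common) == 0L) sk_warn("gene-set intersection is empty")
  list(genes = common,
       venn = data.table(region = c("a_only", "intersection", "b_only"),
                         size = c(length(setdiff(a, b)), length(common),
                                  length(setdiff(b, a)))))
}

#' Rank hub nodes of an induced PPI subgraph
#'
#' Induces the subgraph of the interactome on `nodes` and ranks its members
#' by degree, descending; ties break on the symbol. Nodes absent from the
#' network are retained with degree 0. Ranking is invariant to edge-list row
#' order and orientation.
#'
#' @param edges data.table from [read_edge_list()] (or any two-column
#'   gene-pair table).
#' @param nodes character vector of gene symbols to induce on.
#' @param k number of hubs to return (capped at the node count).
#' @return data.table `gene, degree`, top `k` rows.
#' @export
hub_nodes <- function(edges, nodes, k = 5L) {
  stopifnot(k >= 1L)
  nodes <- sort(unique(toupper(nodes)))
  ed <- as.data.table(edges)
  ed <- ed[toupper(gene_a) %in% nodes & toupper(gene_b) %in% nodes]
  g <- igraph::graph_from_data_frame(
    ed[, .(gene_a, gene_b)], directed = FALSE,
    vertices = data.frame(name = nodes))
  deg <- igraph::degree(g, loops = FALSE)
  out <- data.table(gene = names(deg), degree = as.integer(deg))
  setorderv(out, c("degree", "gene"), order = c(-1L, 1L))
  head(out, min(k, nrow(out)))
}

utils::globalVariables(c("gene_a", "gene_b"))

#' Over-representation analysis with BH-FDR
#'
#' For each annotation term, tests whether the study set is enriched via the
#' upper-tail hypergeometric probability `P(X >= k)` of drawing `k` term
#' members in a sample of size `n` from a universe of `N` genes containing
#' `K` term members. p-values are Benjamini-Hochberg adjusted within each
#' category tag. Study genes outside the universe are dropped (and counted);
#' terms empty after intersection with the universe are skipped.
#'
#' @param study character vector of study gene symbols.
#' @param annotations named list of character vectors (e.g. [read_gmt()]),
#'   or a named list of such lists, where the outer names become category
#'   tags (`BP`, `CC`, `MF`, `pathway`, ...). A flat list gets the single
#'   category `"all"`.
#' @param universe background gene symbols; default: the union of all
#'   annotation sets (a DAVID-like background).
#' @return data.table `category, term, k, K, n_study, N_universe, p, q`,
#'   sorted by `p` ascending; attributes `n_study_dropped` and
#'   `n_terms_skipped`.
#' @export
enrich_gene_sets <- function(study, annotations, universe = NULL) {
  nested <- length(annotations) > 0L && is.list(annotations[[1L]])
  cats <- if (nested) annotations else list(all = annotations)
  if (is.null(universe)) {
    universe <- unique(toupper(unlist(lapply(cats, unlist), use.names = FALSE)))
  } else {
    universe <- unique(toupper(universe))
  }
  study <- unique(toupper(study))
  n_dropped <- sum(!study %in% universe)
  study <- intersect(study, universe)
  n_u <- length(universe)
  n_s <- length(study)

  rows <- list()
  n_skipped <- 0L
  for (cat_name in names(cats)) {
    sets <- cats[[cat_name]]
    for (tm in names(sets)) {
      term_genes <- intersect(unique(toupper(sets[[tm]])), universe)
      K <- length(term_genes)
      if (K == 0L) { n_skipped <- n_skipped + 1L; next }
      k <- length(intersect(term_genes, study))
      p <- phyper(k - 1L, K, n_u - K, n_s, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.table(
        category = cat_name, term = tm, k = k, K = K,
        n_study = n_s, N_universe = n_u, p = p)
    }
  }
  out <- rbindlist(rows)
  if (nrow(out) > 0L) {
    out[, q := p.adjust(p, method = "BH"), by = category]
    setorderv(out, c("p", "term"))
  } else {
    out <- data.table(category = character(0), term = character(0),
                      k = integer(0), K = integer(0), n_study = integer(0),
                      N_universe = integer(0), p = numeric(0), q = numeric(0))
  }
  data.table::setattr(out, "n_study_dropped", n_dropped)
  data.table::setattr(out, "n_terms_skipped", n_skipped)
  out[]
}

#' Top enriched terms
#'
#' Convenience selector mirroring the usual reporting style: the `n` smallest
#' p-value terms, either per category or over the combined table.
#'
#' @param enrichment result of [enrich_gene_sets()].
#' @param n terms to keep.
#' @param per_category when `TRUE` (default), select within each category.
#' @return data.table subset.
#' @export
top_terms <- function(enrichment, n = 10L, per_category = TRUE) {
  dt <- as.data.table(enrichment)
  if (per_category) dt[, head(.SD, n), by = category] else head(dt, n)
}
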