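## Over-representation analysis: GMT catalogs, interaction networks,
## one-sided Fisher exact test, Bonferroni correction, IC scoring and the
## optional network-expanded term-module mode.

#' Build a functional catalog
#'
#' @param category label for the catalog (e.g. `"GO_BP"`, `"KEGG"`).
#' @param termGenes named list: term id -> character vector of gene symbols.
#' @param termNames named character of term descriptions (defaults to ids).
#' @param background gene universe; defaults to the union of all term gene
#'   sets, matching the convention that the universe is the set of genes
#'   annotated anywhere in that ontology.
#' @param ontology optional [OntologyDAG-class] over the term ids, enabling
#'   propagated gene counts for information content.
#' @return a [FunctionalCatalog-class].
#' @export
functionalCatalog <- function(category, termGenes, termNames = NULL,
                              background = NULL, ontology = NULL) {
  termGenes <- lapply(termGenes, function(g) sort(unique(toupper(g))))
  termGenes <- termGenes[lengths(termGenes) > 0L]
  termGenes <- termGenes[order(names(termGenes))]
  if (is.null(background))
    background <- sort(unique(unlist(termGenes, use.names = FALSE)))
  else background <- sort(unique(toupper(background)))
  if (is.null(termNames))
    termNames <- stats::setNames(names(termGenes), names(termGenes))
  termNames <- stats::setNames(as.character(termNames[names(termGenes)]),
                               names(termGenes))
  termNames[is.na(termNames)] <- names(termGenes)[is.na(termNames)]
  new("FunctionalCatalog", category = category, termGenes = termGenes,
      termNames = termNames, background = background, ontology = ontology)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, `term_id TAB description TAB gene...`.
#'
#' @param x path or GMT text.
#' @param category catalog label attached to every term.
#' @inheritParams functionalCatalog
#' @return a [FunctionalCatalog-class].
#' @export
readGMT <- function(x, category, background = NULL, ontology = NULL) {
  lines <- readInput(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    plFormatError("GMT line %d has fewer than 3 fields", bad[[1L]])
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) plFormatError("duplicate GMT term id '%s'",
                                        ids[duplicated(ids)][[1L]])
  descs <- vapply(fields, `[[`, "", 2L)
  genes <- lapply(fields, function(f) f[-(1:2)])
  functionalCatalog(category, stats::setNames(genes, ids),
                    stats::setNames(descs, ids), background, ontology)
}

#' Read a gene-gene interaction network
#'
#' Two-column edge-list TSV (optional third score column, thresholded via
#' `minScore` or ignored). Self-loops are dropped; the graph is undirected
#' and simplified.
#'
#' @param x path or TSV text; a first line starting with a label such as
#'   `gene1`, `protein1`, `node1` or `source` is treated as a header and
#'   skipped.
#' @param minScore drop edges with score below this (requires a third
#'   column); default `NULL` ignores scores.
#' @return an [InteractionNetwork-class].
#' @export
readNetwork <- function(x, minScore = NULL) {
  lines <- readInput(x)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(new("InteractionNetwork",
               graph = igraph::make_empty_graph(0, directed = FALSE)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (tolower(fields[[1L]][[1L]]) %in% c("gene1", "protein1", "node1", "source"))
    fields <- fields[-1L]
  a <- toupper(vapply(fields, `[[`, "", 1L))
  b <- toupper(vapply(fields, `[[`, "", 2L))
  if (!is.null(minScore)) {
    score <- suppressWarnings(as.numeric(vapply(fields, function(f)
      if (length(f) >= 3L) f[[3L]] else NA_character_, "")))
    keep <- !is.na(score) & score >= minScore
    a <- a[keep]; b <- b[keep]
  }
  keep <- a != b
  g <- igraph::graph_from_edgelist(cbind(a[keep], b[keep]), directed = FALSE)
  g <- igraph::simplify(g)
  new("InteractionNetwork", graph = g)
}

#' One-sided Fisher exact over-representation p-value
#'
#' Probability of observing `k` or more query genes inside a term set of
#' size `K`, for a query of size `n` drawn from a background of `N` genes:
#' the upper tail of the hypergeometric distribution, identical to the
#' one-sided Fisher exact test on the 2x2 contingency table.
#'
#' @param k overlap count (query genes annotated with the term).
#' @param K term (or module) gene-set size.
#' @param n query gene-set size.
#' @param N background universe size. All arguments are vectorized.
#' @return `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`.
#' @examples
#' fisherPvalue(4, 10, 5, 100)
#' @export
fisherPvalue <- function(k, K, n, N) {
  len <- max(length(k), length(K), length(n), length(N))
  k <- rep_len(k, len); K <- rep_len(K, len)
  n <- rep_len(n, len); N <- rep_len(N, len)
  if (any(k < 0) || any(K < 0) || any(n < 0) || any(N < 1))
    plDomainError("counts must be non-negative (N >= 1)")
  if (any(K > N) || any(n > N))
    plDomainError("K and n cannot exceed N")
  if (any(k > pmin(K, n)))
    plDomainError("k cannot exceed min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param pRaw raw p-value(s) in (0, 1].
#' @param m number of tests in the family (>= 1).
#' @return `min(1, pRaw * m)`.
#' @export
bonferroni <- function(pRaw, m) {
  if (any(m < 1)) plDomainError("number of tests m must be >= 1")
  if (any(pRaw <= 0) || any(pRaw > 1))
    plDomainError("pRaw must lie in (0, 1]")
  pmin(1, pRaw * m)
}

#' Expand a term gene set into a network module
#'
#' Adds to the term's gene set every connector gene lying on a shortest
#' network path of length at most `maxConnectorPath` between two term
#' genes. With `maxConnectorPath = 0` (or no network) the term set is
#' returned unchanged, i.e. classic over-representation analysis. Term
#' genes absent from the network contribute no paths but stay in the
#' module.
#'
#' @param termGenes character vector of gene symbols.
#' @param network an [InteractionNetwork-class] or `NULL`.
#' @param maxConnectorPath maximum shortest-path length considered
#'   (non-negative integer; a length-2 path has one connector).
#' @return the module gene set (sorted character vector).
#' @export
buildTermModule <- function(termGenes, network, maxConnectorPath = 1L) {
  if (maxConnectorPath < 0) plDomainError("maxConnectorPath must be >= 0")
  termGenes <- sort(unique(termGenes))
  if (is.null(network) || maxConnectorPath == 0L || length(termGenes) < 2L)
    return(termGenes)
  g <- network@graph
  present <- intersect(termGenes, igraph::V(g)$name)
  if (length(present) < 2L) return(termGenes)
  connectors <- character(0)
  d <- igraph::distances(g, v = present, to = present)
  for (i in seq_along(present)[-length(present)]) {
    for (j in seq.int(i + 1L, length(present))) {
      dij <- d[i, j]
      if (is.finite(dij) && dij >= 2 && dij <= maxConnectorPath) {
        sp <- igraph::all_shortest_paths(g, from = present[[i]],
                                         to = present[[j]])$vpaths
        mid <- unlist(lapply(sp, function(p) igraph::V(g)$name[p][-c(1, length(p))]),
                      use.names = FALSE)
        connectors <- c(connectors, mid)
      }
    }
  }
  sort(unique(c(termGenes, connectors)))
}

#' Over-representation analysis of a gene set against a catalog
#'
#' For every term of the catalog, the effective gene set (the term's genes
#' in `standard` mode, or the network-expanded module intersected with the
#' background in `network` mode) is tested for overlap with the query by a
#' one-sided Fisher exact test; raw p-values are Bonferroni-corrected with
#' the number of terms tested (terms with zero overlap count as tested),
#' and significant terms are annotated with their information content.
#'
#' @param query character vector of gene symbols (at least two; the method
#'   requires two or more genes). Query genes outside the catalog
#'   background are dropped with a warning.
#' @param catalog a [FunctionalCatalog-class].
#' @param network an [InteractionNetwork-class], used in `network` mode.
#' @param alpha significance threshold on the corrected p-value
#'   (default 0.05).
#' @param mode `"standard"` (classic ORA) or `"network"` (module-expanded
#'   term sets).
#' @param maxConnectorPath see [buildTermModule()].
#' @param icPropagated when the catalog carries its own ontology, compute
#'   IC on ancestor-propagated gene counts instead of direct counts
#'   (default FALSE: direct counts).
#' @return data.frame of significant terms sorted by corrected p-value
#'   (ascending), then IC (descending, more specific first), then term id;
#'   columns `term_id`, `term_name`, `category`, `k`, `K`, `n`, `N`,
#'   `p_raw`, `p_bonferroni`, `ic`, `hit_genes`, `module_genes`
#'   (';'-joined).
#' @export
enrich <- function(query, catalog, network = NULL, alpha = 0.05,
                   mode = c("standard", "network"), maxConnectorPath = 1L,
                   icPropagated = FALSE) {
  mode <- match.arg(mode)
  query <- sort(unique(toupper(query)))
  if (length(query) < 2L)
    plUsageError("enrichment requires a query of two or more genes (got %d)",
                 length(query))
  emptyEnrichment <- function() data.frame(
    term_id = character(0), term_name = character(0), category = character(0),
    k = integer(0), K = integer(0), n = integer(0), N = integer(0),
    p_raw = numeric(0), p_bonferroni = numeric(0), ic = numeric(0),
    hit_genes = character(0), module_genes = character(0),
    stringsAsFactors = FALSE)
  if (length(catalog@termGenes) == 0L) return(emptyEnrichment())
  dropped <- setdiff(query, catalog@background)
  if (length(dropped)) {
    warning(sprintf("%d query genes outside the %s background were dropped",
                    length(dropped), catalog@category))
    query <- setdiff(query, dropped)
  }
  ## a query that shrinks below the two-gene minimum once restricted to
  ## this catalog's universe has nothing testable here
  if (length(query) < 2L) return(emptyEnrichment())

  N <- length(catalog@background)
  n <- length(query)
  ids <- names(catalog@termGenes)
  m <- length(ids)
  icCounts <- termGeneCounts(catalog, propagated = icPropagated)

  rows <- lapply(ids, function(id) {
    eff <- catalog@termGenes[[id]]
    if (mode == "network")
      eff <- intersect(buildTermModule(eff, network, maxConnectorPath),
                       catalog@background)
    hits <- intersect(query, eff)
    p <- fisherPvalue(length(hits), length(eff), n, N)
    data.frame(
      term_id = id, term_name = unname(catalog@termNames[[id]]),
      category = catalog@category,
      k = length(hits), K = length(eff), n = n, N = N,
      p_raw = p, p_bonferroni = bonferroni(p, m),
      ic = informationContent(icCounts[[id]], N),
      hit_genes = joinSet(hits), module_genes = joinSet(eff),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$p_bonferroni <= alpha, , drop = FALSE]
  res <- res[order(res$p_bonferroni, -res$ic, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

## Direct (or ancestor-propagated, for DAG catalogs) gene counts per term.
termGeneCounts <- function(catalog, propagated = FALSE) {
  if (!propagated || is.null(catalog@ontology))
    return(vapply(catalog@termGenes, length, 0L))
  dag <- catalog@ontology
  vapply(names(catalog@termGenes), function(id) {
    below <- intersect(c(id, termDescendants(dag, id)),
                       names(catalog@termGenes))
    length(unique(unlist(catalog@termGenes[below], use.names = FALSE)))
  }, 0L)
}

#' Write enrichment results
#'
#' @param res enrichment data.frame from [enrich()].
#' @param path output path; format by extension (`.json` or TSV
#'   otherwise).
#' @export
writeEnrichment <- function(res, path) {
  if (grepl("\\.json$", path)) {
    writeCanonicalJSON(res, path)
  } else {
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @describeIn FunctionalCatalog-class compact summary.
#' @param object a `FunctionalCatalog`.
#' @export
setMethod("show", "FunctionalCatalog", function(object) {
  cat(sprintf("FunctionalCatalog [%s]: %d terms, %d background genes\n",
              object@category, length(object@termGenes),
              length(object@background)))
  invisible(NULL)
})

#' @describeIn InteractionNetwork-class compact summary.
#' @param object an `InteractionNetwork`.
#' @export
setMethod("show", "InteractionNetwork", function(object) {
  cat(sprintf("InteractionNetwork: %d genes, %d interactions\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph)))
  invisible(NULL)
})
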