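## Query-side engine: phenotype name/id resolution, per-phenotype general
## analysis and multi-phenotype intersection of diseases, genes and
## enriched terms.

.accessionPattern <- "^[A-Za-z][A-Za-z0-9_]*:[0-9]+$"

#' Resolve phenotype names and identifiers
#'
#' Inputs that look like accessions (`PREFIX:digits`) resolve by exact id
#' match; anything else is matched case-insensitively as a substring of
#' the names and synonyms of non-obsolete terms. Inputs with no match are
#' collected in `unresolved` (reported, never fatal); inputs with several
#' matches return all candidates, and `selected` is the union of all
#' matches.
#'
#' @param inputs character vector of term ids and/or free-text names.
#' @param dag an [OntologyDAG-class].
#' @return a [PhenotypeQuery-class].
#' @export
resolvePhenotypes <- function(inputs, dag) {
  alive <- dag@terms[!dag@terms$obsolete, , drop = FALSE]
  resolved <- list()
  unresolved <- character(0)
  for (q in inputs) {
    hits <- character(0)
    if (grepl(.accessionPattern, q)) {
      if (q %in% alive$term_id) hits <- q
    } else {
      ## literal, case-insensitive substring match over names and synonyms
      needle <- tolower(q)
      nameHit <- grepl(needle, tolower(alive$name), fixed = TRUE)
      synHit <- vapply(alive$term_id, function(id)
        any(grepl(needle, tolower(dag@synonyms[[id]]), fixed = TRUE)),
        logical(1))
      hits <- alive$term_id[nameHit | synHit]
    }
    if (length(hits)) resolved[[q]] <- sort(hits)
    else unresolved <- c(unresolved, q)
  }
  new("PhenotypeQuery", rawInputs = inputs, resolved = resolved,
      unresolved = unresolved,
      selected = as.character(sort(unique(unlist(resolved,
                                                 use.names = FALSE)))))
}

#' General analysis of a single phenotype
#'
#' Collects the diseases and genes (with disease provenance) associated
#' with a phenotype and runs over-representation analysis against every
#' catalog when the phenotype carries at least two genes; below that
#' minimum, enrichment tables are empty and the reason is noted.
#'
#' @param phenotype a resolved term id.
#' @param index a [PhenotypeGeneIndex-class].
#' @param pd a [PhenotypeDiseaseMap-class].
#' @param catalogs list of [FunctionalCatalog-class] objects.
#' @param network optional [InteractionNetwork-class].
#' @param alpha significance threshold (default 0.05).
#' @param mode,maxConnectorPath passed to [enrich()].
#' @return a [GeneralAnalysis-class].
#' @export
generalAnalysis <- function(phenotype, index, pd, catalogs = list(),
                            network = NULL, alpha = 0.05,
                            mode = "standard", maxConnectorPath = 1L) {
  if (!phenotype %in% names(pd@assoc) && !phenotype %in% names(index@genes))
    plLookupError("phenotype '%s' is not in the knowledge base", phenotype)
  diseases <- if (phenotype %in% names(pd@assoc)) pd@assoc[[phenotype]]
              else character(0)
  genes <- if (phenotype %in% names(index@genes)) index@genes[[phenotype]]
           else character(0)
  prov <- if (phenotype %in% names(index@provenance))
    index@provenance[[phenotype]] else structure(list(), names = character(0))

  note <- ""
  enrichments <- list()
  if (length(genes) >= 2L) {
    for (cat in catalogs) {
      enrichments[[cat@category]] <- suppressWarnings(
        enrich(genes, cat, network = network, alpha = alpha, mode = mode,
               maxConnectorPath = maxConnectorPath))
    }
  } else if (length(genes) == 0L) {
    note <- "no molecular information: phenotype has no associated genes"
  } else {
    note <- "below minimum gene count: enrichment requires two or more genes"
  }
  new("GeneralAnalysis", phenotype = phenotype, diseases = diseases,
      genes = genes, provenance = prov, enrichments = enrichments,
      note = note)
}

#' Intersect a set of phenotypes
#'
#' Runs [generalAnalysis()] for every query phenotype, then reports every
#' disease, gene and enriched functional term carried by at least two of
#' them. A term is "carried" by a phenotype when it is enriched at
#' corrected p-value <= `alpha` within that phenotype's own test family.
#' Items carried by the whole query are flagged as full intersection.
#'
#' @param phenotypes character vector of >= 2 distinct resolved term ids;
#'   duplicates are removed with a warning.
#' @inheritParams generalAnalysis
#' @return an [IntersectionReport-class]. Shared terms are sorted by the
#'   number of carrying phenotypes (descending), maximum IC (descending)
#'   and term id.
#' @export
intersectPhenotypes <- function(phenotypes, index, pd, catalogs = list(),
                                network = NULL, alpha = 0.05,
                                mode = "standard", maxConnectorPath = 1L) {
  if (anyDuplicated(phenotypes)) {
    warning("duplicate phenotype ids in query were removed")
    phenotypes <- unique(phenotypes)
  }
  if (length(phenotypes) < 2L)
    plUsageError("intersection requires at least 2 distinct phenotypes (got %d)",
                 length(phenotypes))
  phenotypes <- sort(phenotypes)

  analyses <- stats::setNames(lapply(phenotypes, function(p)
    generalAnalysis(p, index, pd, catalogs, network, alpha, mode,
                    maxConnectorPath)), phenotypes)

  carriedBy <- function(extract) {
    byItem <- list()
    for (p in phenotypes) {
      for (it in extract(analyses[[p]])) byItem[[it]] <- c(byItem[[it]], p)
    }
    byItem <- lapply(byItem, sort)
    byItem <- byItem[lengths(byItem) >= 2L]
    byItem[order(names(byItem))]
  }
  sharedDiseases <- carriedBy(function(a) a@diseases)
  sharedGenes <- carriedBy(function(a) a@genes)

  ## Terms: key on category + term id; keep per-phenotype corrected p.
  termRows <- list()
  for (p in phenotypes) {
    for (tab in analyses[[p]]@enrichments) {
      if (nrow(tab) == 0L) next
      for (i in seq_len(nrow(tab))) {
        key <- paste(tab$category[[i]], tab$term_id[[i]], sep = "\r")
        termRows[[key]] <- rbind(termRows[[key]], data.frame(
          phenotype = p, category = tab$category[[i]],
          term_id = tab$term_id[[i]], term_name = tab$term_name[[i]],
          p_corrected = tab$p_bonferroni[[i]], ic = tab$ic[[i]],
          stringsAsFactors = FALSE))
      }
    }
  }
  termRows <- termRows[vapply(termRows, nrow, 0L) >= 2L]
  sharedTerms <- if (length(termRows)) do.call(rbind, lapply(termRows, function(df) {
    df <- df[order(df$phenotype), , drop = FALSE]
    data.frame(
      category = df$category[[1L]], term_id = df$term_id[[1L]],
      term_name = df$term_name[[1L]], n_phenotypes = nrow(df),
      phenotypes = paste(df$phenotype, collapse = ";"),
      p_corrected = paste(formatC(df$p_corrected, format = "g", digits = 6),
                          collapse = ";"),
      max_ic = max(df$ic),
      full_intersection = nrow(df) == length(phenotypes),
      stringsAsFactors = FALSE)
  })) else data.frame(
    category = character(0), term_id = character(0), term_name = character(0),
    n_phenotypes = integer(0), phenotypes = character(0),
    p_corrected = character(0), max_ic = numeric(0),
    full_intersection = logical(0), stringsAsFactors = FALSE)
  sharedTerms <- sharedTerms[order(-sharedTerms$n_phenotypes,
                                   -sharedTerms$max_ic,
                                   sharedTerms$term_id), , drop = FALSE]
  rownames(sharedTerms) <- NULL

  new("IntersectionReport", query = phenotypes,
      sharedDiseases = sharedDiseases, sharedGenes = sharedGenes,
      sharedTerms = sharedTerms, analyses = analyses, alpha = alpha)
}

#' Shared genes of an intersection report
#'
#' @param report an [IntersectionReport-class].
#' @param fullOnly keep only genes carried by every query phenotype.
#' @return named list: gene -> carrying phenotypes.
#' @export
sharedGenes <- function(report, fullOnly = FALSE) {
  g <- report@sharedGenes
  if (fullOnly) g <- g[lengths(g) == length(report@query)]
  g
}

#' Shared diseases of an intersection report
#' @inheritParams sharedGenes
#' @return named list: disease -> carrying phenotypes.
#' @export
sharedDiseases <- function(report, fullOnly = FALSE) {
  d <- report@sharedDiseases
  if (fullOnly) d <- d[lengths(d) == length(report@query)]
  d
}

#' Shared enriched terms of an intersection report
#' @inheritParams sharedGenes
#' @return data.frame (see [IntersectionReport-class]).
#' @export
sharedTerms <- function(report, fullOnly = FALSE) {
  tt <- report@sharedTerms
  if (fullOnly) tt <- tt[tt$full_intersection, , drop = FALSE]
  tt
}

## Canonical serializable form of a report (stable ordering throughout).
reportAsList <- function(report) {
  list(
    query = report@query,
    alpha = report@alpha,
    shared_diseases = lapply(report@sharedDiseases, as.list),
    shared_genes = lapply(report@sharedGenes, as.list),
    shared_terms = report@sharedTerms,
    unshared_note = "items carried by a single phenotype are omitted"
  )
}

#' Write an intersection report
#'
#' Writes either a single JSON document (sections: query, shared diseases,
#' shared genes, shared terms) or a set of TSV tables
#' (`<prefix>_diseases.tsv`, `<prefix>_genes.tsv`, `<prefix>_terms.tsv`).
#'
#' @param report an [IntersectionReport-class].
#' @param path output path; `.json` for the JSON document, otherwise used
#'   as a prefix for the TSV tables.
#' @return invisibly, the paths written.
#' @export
writeIntersectionReport <- function(report, path) {
  if (grepl("\\.json$", path)) {
    writeCanonicalJSON(reportAsList(report), path)
    return(invisible(path))
  }
  toTable <- function(lst) {
    data.frame(item = names(lst),
               n_phenotypes = as.integer(lengths(lst)),
               phenotypes = vapply(lst, paste, "", collapse = ";"),
               full_intersection = lengths(lst) == length(report@query),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  paths <- paste0(path, c("_diseases.tsv", "_genes.tsv", "_terms.tsv"))
  utils::write.table(toTable(report@sharedDiseases), paths[[1L]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(toTable(report@sharedGenes), paths[[2L]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report@sharedTerms, paths[[3L]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Precompute pairwise intersections
#'
#' Materializes [intersectPhenotypes()] for every unordered pair of the
#' given phenotypes into a directory of JSON files keyed `"P1__P2"` with
#' sorted ids. The stored files are byte-identical to a fresh
#' recomputation.
#'
#' @param phenotypes character vector of term ids (>= 2).
#' @param dir output directory (created if needed).
#' @inheritParams generalAnalysis
#' @return invisibly, a character vector of the files written, named by
#'   pair key.
#' @export
precomputePairwise <- function(phenotypes, dir, index, pd, catalogs = list(),
                               network = NULL, alpha = 0.05,
                               mode = "standard", maxConnectorPath = 1L) {
  phenotypes <- sort(unique(phenotypes))
  if (length(phenotypes) < 2L)
    plUsageError("pairwise store needs at least 2 phenotypes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- character(0)
  for (i in seq_len(length(phenotypes) - 1L)) {
    for (j in seq.int(i + 1L, length(phenotypes))) {
      pair <- c(phenotypes[[i]], phenotypes[[j]])
      key <- paste(pair, collapse = "__")
      rep <- intersectPhenotypes(pair, index, pd, catalogs, network, alpha,
                                 mode, maxConnectorPath)
      f <- file.path(dir, paste0(gsub(":", "_", key), ".json"))
      writeCanonicalJSON(reportAsList(rep), f)
      out[[key]] <- f
    }
  }
  invisible(out)
}

#' @describeIn PhenotypeQuery-class compact summary.
#' @param object a `PhenotypeQuery`.
#' @export
setMethod("show", "PhenotypeQuery", function(object) {
  cat(sprintf("PhenotypeQuery: %d inputs, %d resolved, %d unresolved, %d selected terms\n",
              length(object@rawInputs), length(object@resolved),
              length(object@unresolved), length(object@selected)))
  if (length(object@unresolved))
    cat("  no matching term for:", paste(object@unresolved, collapse = ", "),
        "\n")
  invisible(NULL)
})

#' @describeIn GeneralAnalysis-class compact summary.
#' @param object a `GeneralAnalysis`.
#' @export
setMethod("show", "GeneralAnalysis", function(object) {
  cat(sprintf("GeneralAnalysis of %s: %d diseases, %d genes, %d catalogs\n",
              object@phenotype, length(object@diseases),
              length(object@genes), length(object@enrichments)))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
  invisible(NULL)
})

#' @describeIn IntersectionReport-class compact summary.
#' @param object an `IntersectionReport`.
#' @export
setMethod("show", "IntersectionReport", function(object) {
  full <- sum(lengths(object@sharedGenes) == length(object@query))
  cat(sprintf(
    "IntersectionReport over {%s}:\n  %d shared diseases, %d shared genes (%d in full intersection), %d shared terms\n",
    paste(object@query, collapse = ", "), length(object@sharedDiseases),
    length(object@sharedGenes), full, nrow(object@sharedTerms)))
  invisible(NULL)
})
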