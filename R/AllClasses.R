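## S4 class definitions for the knowledge-graph containers and reports.

setOldClass("igraph")

#' Ontology DAG
#'
#' A directed acyclic graph of ontology terms linked by `is_a` edges, as
#' parsed from an OBO 1.2 stanza file. Obsolete terms are retained for
#' identifier resolution but carry no edges and are excluded from closure,
#' leaf and search queries.
#'
#' @slot terms data.frame with columns `term_id`, `name`, `namespace`,
#'   `obsolete` (one row per term).
#' @slot parents named list mapping each term id to the character vector of
#'   its `is_a` parent ids (empty for roots and obsolete terms).
#' @slot children named list, the reverse adjacency of `parents`.
#' @slot synonyms named list of synonym strings per term.
#' @export
setClass("OntologyDAG", representation(
  terms = "data.frame",
  parents = "list",
  children = "list",
  synonyms = "list"
))

setValidity("OntologyDAG", function(object) {
  tm <- object@terms
  if (!all(c("term_id", "name", "namespace", "obsolete") %in% names(tm)))
    return("terms must have columns term_id, name, namespace, obsolete")
  ids <- tm$term_id
  if (any(!nzchar(ids))) return("empty term id")
  if (anyDuplicated(ids)) return("duplicate term ids")
  if (!setequal(names(object@parents), ids)) return("parents out of sync")
  for (id in ids) {
    p <- object@parents[[id]]
    if (id %in% p) return(sprintf("self-loop at '%s'", id))
    if (!all(p %in% ids))
      return(sprintf("dangling parent reference from '%s'", id))
  }
  ## Kahn's algorithm: every node must be removable.
  indeg <- lengths(object@children)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (p in object@parents[[u]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(ids)) return("is_a relation contains a cycle")
  TRUE
})

#' Phenotype-disease association map
#'
#' @slot assoc named list mapping phenotype term ids to character vectors of
#'   disease ids.
#' @slot propagated logical; whether annotations were extended to all DAG
#'   ancestors.
#' @slot skipped integer; input rows dropped (unknown/obsolete terms,
#'   negated qualifiers).
#' @export
setClass("PhenotypeDiseaseMap", representation(
  assoc = "list", propagated = "logical", skipped = "integer"
))

#' Disease-gene association map
#'
#' @slot assoc named list mapping disease ids to character vectors of
#'   uppercased gene symbols.
#' @export
setClass("DiseaseGeneMap", representation(assoc = "list"))

setValidity("DiseaseGeneMap", function(object) {
  g <- unlist(object@assoc, use.names = FALSE)
  if (length(g) && any(!nzchar(g))) return("empty gene symbol")
  if (length(g) && any(g != toupper(g))) return("gene symbols must be uppercase")
  TRUE
})

#' Per-phenotype gene index with disease provenance
#'
#' Result of collapsing the disease layer: each phenotype maps directly to
#' the union of genes of its associated diseases, and every (phenotype,
#' gene) pair records the mediating diseases.
#'
#' @slot genes named list: phenotype term id -> character vector of genes.
#' @slot provenance named list of named lists: `provenance[[p]][[g]]` is the
#'   character vector of diseases linking phenotype `p` to gene `g`.
#' @slot noGeneInfo character; phenotypes whose diseases have no known genes
#'   (kept with empty gene sets, flagged here).
#' @export
setClass("PhenotypeGeneIndex", representation(
  genes = "list", provenance = "list", noGeneInfo = "character"
))

#' Functional term catalog
#'
#' A GMT-style catalog of term -> gene annotations for one category
#' (GO_BP, GO_MF, GO_CC, KEGG, REACTOME, ...), with its own background
#' gene universe (default: union of all term gene sets).
#'
#' @slot category single label.
#' @slot termGenes named list: term id -> character vector of genes.
#' @slot termNames named character: term id -> description.
#' @slot background character vector of genes, the test universe.
#' @slot ontology an [OntologyDAG-class] over the term ids, or `NULL`; used
#'   only when information content is computed on propagated counts.
#' @export
setClass("FunctionalCatalog", representation(
  category = "character", termGenes = "list", termNames = "character",
  background = "character", ontology = "ANY"
))

setValidity("FunctionalCatalog", function(object) {
  if (length(object@category) != 1L) return("category must be length 1")
  if (any(lengths(object@termGenes) == 0L))
    return("empty term gene set after load")
  g <- unlist(object@termGenes, use.names = FALSE)
  if (!all(g %in% object@background))
    return("term genes outside background universe")
  TRUE
})

#' Gene-gene interaction network
#'
#' Undirected simple graph over gene symbols (no self-loops, no multiple
#' edges), used to expand term gene sets with shortest-path connectors.
#'
#' @slot graph an igraph object.
#' @export
setClass("InteractionNetwork", representation(graph = "igraph"))

setValidity("InteractionNetwork", function(object) {
  g <- object@graph
  if (igraph::is_directed(g)) return("network must be undirected")
  if (any(igraph::which_loop(g))) return("self-loops not allowed")
  TRUE
})

#' Resolved phenotype query
#'
#' @slot rawInputs the strings given by the user (ids or names).
#' @slot resolved named list: input -> character vector of matching term ids.
#' @slot unresolved inputs with no match in the ontology.
#' @slot selected final deduplicated list of term ids.
#' @export
setClass("PhenotypeQuery", representation(
  rawInputs = "character", resolved = "list", unresolved = "character",
  selected = "character"
))

setValidity("PhenotypeQuery", function(object) {
  res <- names(object@resolved)
  if (!setequal(object@rawInputs, c(res, object@unresolved)))
    return("resolved and unresolved must partition rawInputs")
  if (length(intersect(res, object@unresolved)))
    return("an input cannot be both resolved and unresolved")
  TRUE
})

#' Per-phenotype general analysis
#'
#' Diseases, genes (with disease provenance) and per-category enrichment
#' tables for one phenotype.
#'
#' @slot phenotype term id.
#' @slot diseases character vector of associated disease ids.
#' @slot genes character vector of associated genes.
#' @slot provenance named list: gene -> mediating diseases.
#' @slot enrichments named list: category -> enrichment result data.frame.
#' @slot note reason string when enrichment was not run (e.g. fewer than the
#'   minimum of two genes), otherwise empty.
#' @export
setClass("GeneralAnalysis", representation(
  phenotype = "character", diseases = "character", genes = "character",
  provenance = "list", enrichments = "list", note = "character"
))

#' Multi-phenotype intersection report
#'
#' @slot query sorted character vector of query phenotype term ids.
#' @slot sharedDiseases named list: disease id -> sorted character vector of
#'   carrying query phenotypes (always >= 2).
#' @slot sharedGenes named list: gene -> carrying query phenotypes (>= 2).
#' @slot sharedTerms data.frame with columns `category`, `term_id`,
#'   `term_name`, `n_phenotypes`, `phenotypes`, `p_corrected`, `max_ic`,
#'   `full_intersection`; `phenotypes` and `p_corrected` are ';'-joined and
#'   aligned.
#' @slot analyses named list of [GeneralAnalysis-class], one per query
#'   phenotype.
#' @slot alpha significance threshold used for term carrying.
#' @export
setClass("IntersectionReport", representation(
  query = "character", sharedDiseases = "list", sharedGenes = "list",
  sharedTerms = "data.frame", analyses = "list", alpha = "numeric"
))

setValidity("IntersectionReport", function(object) {
  if (any(lengths(object@sharedDiseases) < 2L))
    return("shared diseases must be carried by >= 2 phenotypes")
  if (any(lengths(object@sharedGenes) < 2L))
    return("shared genes must be carried by >= 2 phenotypes")
  TRUE
})

#' Synthetic fixture configuration
#'
#' Seeded configuration for the toy input-bundle generator; the seed fully
#' determines the bundle.
#'
#' @slot seed integer RNG seed.
#' @slot nInternalTerms,nLeafTerms DAG shape (internal layer terms, leaves).
#' @slot dagParentsPerTerm maximum parents sampled per term.
#' @slot nDiseases number of background diseases.
#' @slot phenotypesPerDisease,genesPerDisease inclusive integer ranges
#'   (length 2).
#' @slot nGenesBackground size of the gene symbol pool.
#' @slot nFunctionalTerms named integer: random terms per catalog category.
#' @slot planted list with `nTargetPhenotypes`, `nPlantedGenes`,
#'   `plantedCategory`, `coverage` (fraction of the targets' collapsed gene
#'   union covered by the planted term).
#' @slot noise per-table spurious-row rate.
#' @slot networkDegree mean degree of the random interaction network.
#' @slot nBlindDiseases blind-set diseases built on the planted signal.
#' @export
setClass("FixtureConfig", representation(
  seed = "integer", nInternalTerms = "integer", nLeafTerms = "integer",
  dagParentsPerTerm = "integer", nDiseases = "integer",
  phenotypesPerDisease = "integer", genesPerDisease = "integer",
  nGenesBackground = "integer", nFunctionalTerms = "integer",
  planted = "list", noise = "numeric", networkDegree = "numeric",
  nBlindDiseases = "integer"
))

setValidity("FixtureConfig", function(object) {
  cov <- object@planted$coverage
  if (!is.numeric(cov) || cov <= 0 || cov > 1)
    return("planted coverage must lie in (0, 1]")
  counts <- c(object@nInternalTerms, object@nLeafTerms, object@nDiseases,
              object@nGenesBackground, object@nFunctionalTerms)
  if (any(counts <= 0L)) return("all counts must be positive")
  if (object@noise < 0) return("noise rate must be >= 0")
  if (length(object@phenotypesPerDisease) != 2L ||
      length(object@genesPerDisease) != 2L)
    return("per-disease ranges must have length 2")
  TRUE
})

#' Synthetic fixture bundle
#'
#' Complete toy input set (ontology, association tables, catalogs, network,
#' blind set) emitted as in-memory text in the exact formats the loaders
#' consume, plus the planted truth.
#'
#' @slot oboText OBO-format ontology text.
#' @slot phenotypeDiseaseTsv,diseaseGeneTsv,networkTsv,blindSetTsv TSV text.
#' @slot gmt named list: category -> GMT text.
#' @slot truth list describing the planted signal (target phenotypes,
#'   planted genes and term, blind-disease truth).
#' @export
setClass("FixtureBundle", representation(
  oboText = "character", phenotypeDiseaseTsv = "character",
  diseaseGeneTsv = "character", gmt = "list", networkTsv = "character",
  blindSetTsv = "character", truth = "list"
))

#' Blind-set recovery metrics
#'
#' @slot nDiseases evaluable blind diseases.
#' @slot nRecoveredDiseases diseases with >= 1 truth gene retrieved.
#' @slot diseaseRecoveryFraction nRecoveredDiseases / nDiseases.
#' @slot nTruthGenes truth (disease, gene) pairs pooled over diseases.
#' @slot nRecoveredGenes truth pairs retrieved.
#' @slot geneRecoveryFraction nRecoveredGenes / nTruthGenes.
#' @slot perDisease data.frame with one row per disease: id, phenotypes
#'   used, retrieved shared genes, truth genes, hits, recovered flag,
#'   evaluable flag.
#' @export
setClass("RecoveryMetrics", representation(
  nDiseases = "integer", nRecoveredDiseases = "integer",
  diseaseRecoveryFraction = "numeric", nTruthGenes = "integer",
  nRecoveredGenes = "integer", geneRecoveryFraction = "numeric",
  perDisease = "data.frame"
))

setValidity("RecoveryMetrics", function(object) {
  f <- c(object@diseaseRecoveryFraction, object@geneRecoveryFraction)
  f <- f[!is.nan(f)]
  if (any(f < 0 | f > 1)) return("recovery fractions must lie in [0, 1]")
  if (object@nRecoveredGenes > object@nTruthGenes)
    return("recovered genes cannot exceed truth genes")
  TRUE
})
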