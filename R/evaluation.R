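## Blind-set evaluation: recover causative genes of held-out diseases from
## their phenotype lists via the intersection engine.

#' Load a blind evaluation set
#'
#' TSV with columns `disease_id`, `phenotype_ids` (';'-joined) and
#' `gene_symbols` (';'-joined). Two filters are applied on load: diseases
#' listed in `exclude` (i.e. already part of the training knowledge base)
#' are dropped, and so are diseases with fewer than two phenotypes — a
#' single phenotype cannot be intersected.
#'
#' @param x path or TSV text.
#' @param exclude character vector of disease ids to drop.
#' @return data.frame with columns `disease_id`, `phenotypes` (list
#'   column), `genes` (list column, uppercased); attributes
#'   `nExcluded` and `nTooFewPhenotypes` count the filtered rows.
#' @export
loadBlindSet <- function(x, exclude = character(0)) {
  df <- readTsv(x)
  need <- c("disease_id", "phenotype_ids", "gene_symbols")
  if (!all(need %in% names(df)))
    plFormatError("blind-set table needs columns %s; found: %s",
                  paste(need, collapse = ", "), paste(names(df), collapse = ", "))
  asChr <- function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }
  phen <- splitSet(asChr(df$phenotype_ids))
  genes <- lapply(splitSet(asChr(df$gene_symbols)), toupper)
  bad <- which(lengths(genes) == 0L | lengths(phen) == 0L |
                 !nzchar(asChr(df$disease_id)))
  if (length(bad))
    plFormatError("malformed blind-set row at line %d (empty disease or gene list)",
                  bad[[1L]] + 1L)

  excluded <- df$disease_id %in% exclude
  tooFew <- lengths(phen) < 2L
  keep <- !excluded & !tooFew
  out <- data.frame(disease_id = df$disease_id[keep],
                    stringsAsFactors = FALSE)
  out$phenotypes <- phen[keep]
  out$genes <- genes[keep]
  attr(out, "nExcluded") <- sum(excluded)
  attr(out, "nTooFewPhenotypes") <- sum(tooFew & !excluded)
  out
}

#' Evaluate gene recovery on a blind set
#'
#' For each held-out disease, the query is its phenotype list: the
#' intersection engine retrieves the genes shared by at least two of the
#' phenotypes (or by all of them with `strictAll = TRUE`), and the disease
#' counts as recovered when at least one of its known causative genes is
#' in that list. Gene-level recovery pools every (disease, truth gene)
#' pair across the blind set. Phenotypes absent from the ontology are
#' skipped with a warning; a disease is evaluable only if at least two of
#' its phenotypes remain.
#'
#' @param blind data.frame from [loadBlindSet()].
#' @param dag an [OntologyDAG-class].
#' @param index a [PhenotypeGeneIndex-class].
#' @param pd a [PhenotypeDiseaseMap-class].
#' @param strictAll require genes shared by every phenotype of the disease
#'   (default FALSE: shared by >= 2).
#' @param widenToUnion use the union of per-phenotype gene sets instead of
#'   the shared list (sensitivity analysis; default FALSE).
#' @return a [RecoveryMetrics-class].
#' @export
evaluateBlindSet <- function(blind, dag, index, pd, strictAll = FALSE,
                             widenToUnion = FALSE) {
  rows <- list()
  for (i in seq_len(nrow(blind))) {
    d <- blind$disease_id[[i]]
    phen <- blind$phenotypes[[i]]
    truth <- sort(unique(blind$genes[[i]]))
    known <- phen[phen %in% dag@terms$term_id &
                    !dag@terms$obsolete[match(phen, dag@terms$term_id)]]
    known <- intersect(known, names(index@genes))
    if (length(known) < length(phen))
      warning(sprintf("disease %s: %d phenotype ids not in the knowledge base were skipped",
                      d, length(phen) - length(known)))
    if (length(unique(known)) < 2L) {
      rows[[i]] <- data.frame(
        disease_id = d, n_phenotypes_used = length(unique(known)),
        retrieved_genes = "", truth_genes = joinSet(truth), hits = "",
        n_hits = 0L, recovered = FALSE, evaluable = FALSE,
        stringsAsFactors = FALSE)
      next
    }
    retrieved <- if (widenToUnion) {
      sort(unique(unlist(index@genes[unique(known)], use.names = FALSE)))
    } else {
      rep <- intersectPhenotypes(unique(known), index, pd, catalogs = list())
      names(sharedGenes(rep, fullOnly = strictAll))
    }
    hits <- intersect(truth, retrieved)
    rows[[i]] <- data.frame(
      disease_id = d, n_phenotypes_used = length(unique(known)),
      retrieved_genes = joinSet(retrieved), truth_genes = joinSet(truth),
      hits = joinSet(hits), n_hits = length(hits),
      recovered = length(hits) > 0L, evaluable = TRUE,
      stringsAsFactors = FALSE)
  }
  perDisease <- if (length(rows)) do.call(rbind, rows) else data.frame(
    disease_id = character(0), n_phenotypes_used = integer(0),
    retrieved_genes = character(0), truth_genes = character(0),
    hits = character(0), n_hits = integer(0), recovered = logical(0),
    evaluable = logical(0), stringsAsFactors = FALSE)
  ev <- perDisease[perDisease$evaluable, , drop = FALSE]
  nTruth <- sum(vapply(seq_len(nrow(blind)), function(i)
    length(unique(blind$genes[[i]])), 0L)[blind$disease_id %in% ev$disease_id])
  nDis <- nrow(ev)
  nRec <- sum(ev$recovered)
  nHit <- sum(ev$n_hits)
  new("RecoveryMetrics",
      nDiseases = as.integer(nDis), nRecoveredDiseases = as.integer(nRec),
      diseaseRecoveryFraction = if (nDis) nRec / nDis else NaN,
      nTruthGenes = as.integer(nTruth), nRecoveredGenes = as.integer(nHit),
      geneRecoveryFraction = if (nTruth) nHit / nTruth else NaN,
      perDisease = perDisease)
}

#' Write recovery metrics
#'
#' Writes the summary as JSON and the per-disease breakdown as TSV.
#'
#' @param metrics a [RecoveryMetrics-class].
#' @param jsonPath path for the JSON summary.
#' @param tsvPath optional path for the per-disease TSV.
#' @export
writeRecoveryMetrics <- function(metrics, jsonPath, tsvPath = NULL) {
  writeCanonicalJSON(list(
    n_diseases = metrics@nDiseases,
    n_recovered_diseases = metrics@nRecoveredDiseases,
    disease_recovery_fraction = metrics@diseaseRecoveryFraction,
    n_truth_genes = metrics@nTruthGenes,
    n_recovered_genes = metrics@nRecoveredGenes,
    gene_recovery_fraction = metrics@geneRecoveryFraction
  ), jsonPath)
  if (!is.null(tsvPath))
    utils::write.table(metrics@perDisease, tsvPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(jsonPath)
}

#' @describeIn RecoveryMetrics-class compact summary.
#' @param object a `RecoveryMetrics`.
#' @export
setMethod("show", "RecoveryMetrics", function(object) {
  cat(sprintf(
    "RecoveryMetrics: %d/%d diseases recovered (%.1f%%); %d/%d truth genes recovered (%.1f%%)\n",
    object@nRecoveredDiseases, object@nDiseases,
    100 * object@diseaseRecoveryFraction,
    object@nRecoveredGenes, object@nTruthGenes,
    100 * object@geneRecoveryFraction))
  invisible(NULL)
})
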