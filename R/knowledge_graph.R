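## Phenotype-disease and disease-gene tables, ancestor propagation, and
## collapse of the disease layer into per-phenotype gene sets.

## HPOA-dialect column candidates; a plain (disease_id, phenotype_id) TSV
## works too.
.diseaseCols <- c("disease_id", "database_id")
.phenotypeCols <- c("phenotype_id", "hpo_id")

#' Load a phenotype-disease association table
#'
#' Reads a TSV (HPOA dialect or plain two-column) of phenotype-disease
#' links. Rows carrying the negation qualifier `NOT` are dropped. Rows
#' referencing unknown or obsolete phenotype terms are skipped with a
#' warning and counted in the result. When `propagate = TRUE`, every
#' association of a phenotype is extended to all its ancestors in the DAG,
#' so that each term accumulates the diseases of its whole descendant
#' subtree.
#'
#' @param x path or TSV text with columns `disease_id` (or `database_id`)
#'   and `phenotype_id` (or `hpo_id`); an optional `qualifier` column may
#'   mark negated rows with `NOT`. Lines starting with `#` are comments.
#' @param dag an [OntologyDAG-class] the phenotype ids refer to.
#' @param propagate extend annotations to all DAG ancestors (default TRUE).
#' @param diseasePrefix prefix applied to bare numeric disease ids
#'   (default `"OMIM"`, yielding `OMIM:123456`).
#' @return a [PhenotypeDiseaseMap-class].
#' @export
loadPhenotypeDisease <- function(x, dag, propagate = TRUE,
                                 diseasePrefix = "OMIM") {
  df <- readTsv(x)
  if (nrow(df) == 0L) {
    warning("empty phenotype-disease table")
    return(new("PhenotypeDiseaseMap", assoc = structure(list(), names = character(0)),
               propagated = propagate, skipped = 0L))
  }
  dCol <- pickColumn(df, .diseaseCols)
  pCol <- pickColumn(df, .phenotypeCols)
  if (is.na(dCol) || is.na(pCol))
    plFormatError(
      "phenotype-disease table needs columns (%s) and (%s); found: %s",
      paste(.diseaseCols, collapse = "|"),
      paste(.phenotypeCols, collapse = "|"),
      paste(names(df), collapse = ", "))

  if ("qualifier" %in% names(df))
    df <- df[is.na(df$qualifier) | df$qualifier != "NOT", , drop = FALSE]

  disease <- normalizeDiseaseId(as.character(df[[dCol]]), diseasePrefix)
  pheno <- as.character(df[[pCol]])

  known <- pheno %in% dag@terms$term_id
  obsolete <- known & dag@terms$obsolete[match(pheno, dag@terms$term_id)]
  keep <- known & !obsolete
  nSkipped <- sum(!keep)
  if (nSkipped > 0L)
    warning(sprintf("skipped %d rows with unknown or obsolete phenotype terms",
                    nSkipped))
  disease <- disease[keep]; pheno <- pheno[keep]

  assoc <- lapply(split(disease, pheno), function(d) sort(unique(d)))
  if (propagate) assoc <- propagateAssoc(assoc, dag)
  assoc <- assoc[order(names(assoc))]
  new("PhenotypeDiseaseMap", assoc = assoc, propagated = propagate,
      skipped = nSkipped)
}

normalizeDiseaseId <- function(x, prefix) {
  bare <- grepl("^#?[0-9]+$", x)
  x[bare] <- paste0(prefix, ":", sub("^#", "", x[bare]))
  x
}

## Push every term's diseases to all of its ancestors (set union; diamond
## paths deduplicate). Idempotent: a second pass changes nothing.
propagateAssoc <- function(assoc, dag) {
  out <- assoc
  for (p in names(assoc)) {
    for (a in termAncestors(dag, p)) {
      out[[a]] <- sort(unique(c(out[[a]], assoc[[p]])))
    }
  }
  out[order(names(out))]
}

#' Load a disease-gene association table
#'
#' Generic two-column TSV (`disease_id`, `gene_symbol`); duplicate rows
#' collapse to set semantics and gene symbols are uppercased on load.
#'
#' @param x path or TSV text.
#' @param diseasePrefix prefix for bare numeric disease ids.
#' @return a [DiseaseGeneMap-class].
#' @export
loadDiseaseGene <- function(x, diseasePrefix = "OMIM") {
  df <- readTsv(x)
  if (nrow(df) == 0L) {
    warning("empty disease-gene table")
    return(new("DiseaseGeneMap", assoc = structure(list(), names = character(0))))
  }
  dCol <- pickColumn(df, .diseaseCols)
  gCol <- pickColumn(df, c("gene_symbol", "gene"))
  if (is.na(dCol) || is.na(gCol))
    plFormatError("disease-gene table needs columns disease_id and gene_symbol; found: %s",
                  paste(names(df), collapse = ", "))
  disease <- normalizeDiseaseId(as.character(df[[dCol]]), diseasePrefix)
  gene <- toupper(trimws(as.character(df[[gCol]])))
  ok <- nzchar(gene)
  assoc <- lapply(split(gene[ok], disease[ok]), function(g) sort(unique(g)))
  new("DiseaseGeneMap", assoc = assoc[order(names(assoc))])
}

#' Collapse the disease layer into a phenotype-gene index
#'
#' Joins the phenotype-disease and disease-gene maps: each phenotype maps
#' directly to the union of the genes of its diseases, and every
#' (phenotype, gene) pair records its mediating diseases. Phenotypes whose
#' diseases have no known genes are kept with empty gene sets and flagged,
#' so queries on them can report the absence of molecular information
#' rather than fail.
#'
#' @param pd a [PhenotypeDiseaseMap-class].
#' @param dg a [DiseaseGeneMap-class].
#' @return a [PhenotypeGeneIndex-class].
#' @export
collapseDiseaseLayer <- function(pd, dg) {
  phenos <- names(pd@assoc)
  genes <- stats::setNames(vector("list", length(phenos)), phenos)
  prov <- stats::setNames(vector("list", length(phenos)), phenos)
  noInfo <- character(0)
  for (p in phenos) {
    gp <- list()
    for (d in pd@assoc[[p]]) {
      for (g in dg@assoc[[d]]) gp[[g]] <- c(gp[[g]], d)
    }
    gs <- if (length(gp)) sort(names(gp)) else character(0)
    genes[[p]] <- gs
    prov[[p]] <- lapply(gp[gs], function(d) sort(unique(d)))
    if (length(gs) == 0L) noInfo <- c(noInfo, p)
  }
  new("PhenotypeGeneIndex", genes = genes, provenance = prov,
      noGeneInfo = sort(noInfo))
}

#' Genes associated with a phenotype
#' @param index a [PhenotypeGeneIndex-class].
#' @param phenotype a term id present in the index.
#' @export
phenotypeGenes <- function(index, phenotype) {
  if (!phenotype %in% names(index@genes))
    plLookupError("phenotype '%s' not in index", phenotype)
  index@genes[[phenotype]]
}

#' Mediating diseases of a (phenotype, gene) pair
#' @inheritParams phenotypeGenes
#' @param gene a gene symbol carried by `phenotype`.
#' @export
geneProvenance <- function(index, phenotype, gene) {
  if (!phenotype %in% names(index@provenance))
    plLookupError("phenotype '%s' not in index", phenotype)
  d <- index@provenance[[phenotype]][[gene]]
  if (is.null(d))
    plLookupError("gene '%s' not associated with phenotype '%s'",
                  gene, phenotype)
  d
}

#' Summary statistics of the knowledge graph
#'
#' Counts of phenotypes, diseases and genes, the histogram of leaf
#' phenotypes per disease, and the most-annotated disease — the usual
#' first-look report on a freshly built knowledge base.
#'
#' @param pd a [PhenotypeDiseaseMap-class].
#' @param dg a [DiseaseGeneMap-class].
#' @param index a [PhenotypeGeneIndex-class] built from the two maps.
#' @param dag the [OntologyDAG-class] used for leaf identification.
#' @return a list with elements `nPhenotypes`, `nDiseases`, `nGenes`,
#'   `leafPhenotypesPerDisease` (named integer histogram:
#'   count-of-leaves -> number of diseases), `maxAnnotatedDisease` and
#'   `maxLeafPhenotypes`.
#' @export
associationStats <- function(pd, dg, index, dag) {
  leaves <- dagLeaves(dag)
  perDisease <- list()
  for (p in intersect(names(pd@assoc), leaves)) {
    for (d in pd@assoc[[p]]) perDisease[[d]] <- c(perDisease[[d]], p)
  }
  counts <- vapply(perDisease, function(v) length(unique(v)), 0L)
  hist <- if (length(counts)) table(counts) else table(integer(0))
  hist <- stats::setNames(as.integer(hist), names(hist))
  allDiseases <- unique(c(unlist(pd@assoc, use.names = FALSE), names(dg@assoc)))
  maxD <- if (length(counts)) names(perDisease)[which.max(counts)] else NA_character_
  list(
    nPhenotypes = length(pd@assoc),
    nDiseases = length(allDiseases),
    nGenes = length(unique(unlist(index@genes, use.names = FALSE))),
    leafPhenotypesPerDisease = hist,
    maxAnnotatedDisease = maxD,
    maxLeafPhenotypes = if (length(counts)) max(counts) else 0L
  )
}

#' Write the collapsed index as TSV
#'
#' One row per (phenotype, gene) pair with the mediating diseases
#' ';'-joined.
#'
#' @param index a [PhenotypeGeneIndex-class].
#' @param path output file path.
#' @export
writeGeneIndex <- function(index, path) {
  rows <- list()
  for (p in names(index@genes)) {
    for (g in index@genes[[p]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        phenotype_id = p, gene_symbol = g,
        diseases = joinSet(index@provenance[[p]][[g]]),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(phenotype_id = character(0), gene_symbol = character(0),
               diseases = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @describeIn PhenotypeDiseaseMap-class compact summary.
#' @param object a `PhenotypeDiseaseMap`.
#' @export
setMethod("show", "PhenotypeDiseaseMap", function(object) {
  cat(sprintf(
    "PhenotypeDiseaseMap: %d phenotypes, %d diseases (%spropagated, %d rows skipped)\n",
    length(object@assoc),
    length(unique(unlist(object@assoc, use.names = FALSE))),
    if (object@propagated) "" else "not ", object@skipped))
  invisible(NULL)
})

#' @describeIn PhenotypeGeneIndex-class compact summary.
#' @param object a `PhenotypeGeneIndex`.
#' @export
setMethod("show", "PhenotypeGeneIndex", function(object) {
  cat(sprintf(
    "PhenotypeGeneIndex: %d phenotypes, %d genes (%d phenotypes without gene info)\n",
    length(object@genes),
    length(unique(unlist(object@genes, use.names = FALSE))),
    length(object@noGeneInfo)))
  invisible(NULL)
})
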