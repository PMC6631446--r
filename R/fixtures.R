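## Seeded synthetic fixture generator: a toy ontology, association tables,
## catalogs, network and blind set with a planted shared functional signal,
## so the whole pipeline is testable without any external download.

## sample() without the length-1 surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Synthetic fixture configuration
#'
#' Defaults describe a small but non-degenerate knowledge base: a two-layer
#' random DAG, a dozen diseases with the multi-phenotype multiplicity seen
#' in real disease annotation (most diseases annotate several leaves), a
#' gene pool an order of magnitude larger than any per-phenotype gene set,
#' and one planted functional term that covers the target phenotypes'
#' collapsed gene sets completely (`coverage = 1`). The seed fully
#' determines the bundle.
#'
#' @param seed integer RNG seed.
#' @param nInternalTerms,nLeafTerms DAG shape.
#' @param dagParentsPerTerm max parents sampled per term.
#' @param nDiseases background diseases.
#' @param phenotypesPerDisease,genesPerDisease inclusive ranges (length 2).
#' @param nGenesBackground gene symbol pool size.
#' @param nFunctionalTerms named integer vector: random terms per category.
#' @param nTargetPhenotypes,nPlantedGenes,plantedCategory,coverage planted
#'   signal: number of target leaf phenotypes, number of planted causative
#'   genes shared by all of them, catalog carrying the planted term, and
#'   the fraction of the targets' collapsed gene union covered by that
#'   term.
#' @param noise per-table spurious-row rate (fraction of clean rows).
#' @param networkDegree mean degree of the random part of the interaction
#'   network.
#' @param nBlindDiseases held-out diseases built on the planted signal.
#' @return a [FixtureConfig-class].
#' @export
fixtureConfig <- function(seed = 1L,
                          nInternalTerms = 10L, nLeafTerms = 16L,
                          dagParentsPerTerm = 2L,
                          nDiseases = 12L,
                          phenotypesPerDisease = c(2L, 5L),
                          genesPerDisease = c(1L, 3L),
                          nGenesBackground = 120L,
                          nFunctionalTerms = c(GO_BP = 15L, KEGG = 8L),
                          nTargetPhenotypes = 3L,
                          nPlantedGenes = 6L,
                          plantedCategory = "GO_BP",
                          coverage = 1.0,
                          noise = 0,
                          networkDegree = 2,
                          nBlindDiseases = 4L) {
  if (!plantedCategory %in% names(nFunctionalTerms))
    plConfigError("plantedCategory '%s' is not among the catalog categories",
                  plantedCategory)
  if (nTargetPhenotypes > nLeafTerms)
    plConfigError("more target phenotypes than leaves")
  if (nPlantedGenes > nGenesBackground)
    plConfigError("planted coverage demands more genes than exist")
  new("FixtureConfig",
      seed = as.integer(seed), nInternalTerms = as.integer(nInternalTerms),
      nLeafTerms = as.integer(nLeafTerms),
      dagParentsPerTerm = as.integer(dagParentsPerTerm),
      nDiseases = as.integer(nDiseases),
      phenotypesPerDisease = as.integer(phenotypesPerDisease),
      genesPerDisease = as.integer(genesPerDisease),
      nGenesBackground = as.integer(nGenesBackground),
      nFunctionalTerms = stats::setNames(as.integer(nFunctionalTerms),
                                         names(nFunctionalTerms)),
      planted = list(nTargetPhenotypes = as.integer(nTargetPhenotypes),
                     nPlantedGenes = as.integer(nPlantedGenes),
                     plantedCategory = plantedCategory,
                     coverage = coverage),
      noise = noise, networkDegree = networkDegree,
      nBlindDiseases = as.integer(nBlindDiseases))
}

#' Generate a synthetic fixture bundle
#'
#' Builds, as in-memory text in the exact formats the loaders consume:
#' (i) a random rooted DAG (topological layering, so acyclic by
#' construction) with one obsolete term; (ii) diseases annotated to
#' several random leaves; (iii) disease-gene assignments; (iv) GMT
#' catalogs whose planted term covers the target phenotypes' collapsed
#' gene sets at the configured fraction, plus random background terms;
#' (v) an interaction network connecting the planted genes through one
#' connector hub; (vi) a blind set of extra diseases reusing the target
#' phenotypes with planted truth genes. The same config yields a
#' byte-identical bundle.
#'
#' @param config a [FixtureConfig-class].
#' @return a [FixtureBundle-class].
#' @export
generateFixture <- function(config) {
  withSeed(config@seed, generateFixtureImpl(config))
}

generateFixtureImpl <- function(config) {
  pl <- config@planted

  ## --- ontology: root -> internal layers -> leaves ---------------------
  rootId <- "SP:0000001"
  internal <- sprintf("SP:%07d", seq_len(config@nInternalTerms) + 1L)
  leaves <- sprintf("SP:%07d", seq_len(config@nLeafTerms) + 1L +
                      config@nInternalTerms)
  obsoleteId <- "SP:0999999"
  parents <- list()
  parents[[rootId]] <- character(0)
  for (i in seq_along(internal)) {
    pool <- c(rootId, internal[seq_len(i - 1L)])
    k <- min(length(pool), sample.int(config@dagParentsPerTerm, 1L))
    parents[[internal[[i]]]] <- sort(resample(pool, k))
  }
  for (l in leaves) {
    k <- min(length(internal), sample.int(config@dagParentsPerTerm, 1L))
    parents[[l]] <- sort(resample(internal, k))
  }

  oboLines <- c("format-version: 1.2", "ontology: synthetic-phenotypes", "")
  addTerm <- function(id, name, isA, obsolete = FALSE) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      if (length(isA)) paste0("is_a: ", isA, " ! parent"),
      if (obsolete) "is_obsolete: true", "")
  }
  oboLines <- c(oboLines, addTerm(rootId, "synthetic phenotypic abnormality",
                                  character(0)))
  for (i in seq_along(internal))
    oboLines <- c(oboLines, addTerm(internal[[i]],
                                    sprintf("synthetic category %02d", i),
                                    parents[[internal[[i]]]]))
  for (i in seq_along(leaves))
    oboLines <- c(oboLines, addTerm(leaves[[i]],
                                    sprintf("synthetic phenotype %02d", i),
                                    parents[[leaves[[i]]]]))
  oboLines <- c(oboLines, addTerm(obsoleteId, "retired synthetic phenotype",
                                  character(0), obsolete = TRUE))

  ## --- genes, targets, planted signal ----------------------------------
  genePool <- sprintf("GENE%04d", seq_len(config@nGenesBackground))
  plantedGenes <- genePool[seq_len(pl$nPlantedGenes)]
  targets <- sort(resample(leaves, pl$nTargetPhenotypes))

  ## background diseases over random leaves and random genes
  pdRows <- list(); dgRows <- list()
  for (i in seq_len(config@nDiseases)) {
    d <- sprintf("MIM:6%05d", i)
    np <- resample(seq.int(config@phenotypesPerDisease[[1L]],
                           config@phenotypesPerDisease[[2L]]), 1L)
    ng <- resample(seq.int(config@genesPerDisease[[1L]],
                           config@genesPerDisease[[2L]]), 1L)
    for (p in sort(resample(leaves, min(np, length(leaves)))))
      pdRows[[length(pdRows) + 1L]] <- c(d, p)
    for (g in sort(resample(genePool, ng)))
      dgRows[[length(dgRows) + 1L]] <- c(d, g)
  }
  ## planted diseases: one per target, carrying every planted gene
  for (i in seq_along(targets)) {
    d <- sprintf("MIM:69%04d", i)
    pdRows[[length(pdRows) + 1L]] <- c(d, targets[[i]])
    for (g in plantedGenes) dgRows[[length(dgRows) + 1L]] <- c(d, g)
  }

  ## collapsed gene sets of the targets on the clean tables define the
  ## planted term; spurious rows added afterwards dilute, never help
  geneOf <- split(vapply(dgRows, `[[`, "", 2L), vapply(dgRows, `[[`, "", 1L))
  disOf <- split(vapply(pdRows, `[[`, "", 1L), vapply(pdRows, `[[`, "", 2L))
  targetUnion <- sort(unique(unlist(lapply(targets, function(p)
    unlist(geneOf[disOf[[p]]], use.names = FALSE)), use.names = FALSE)))
  nCover <- max(1L, ceiling(pl$coverage * length(targetUnion)))
  plantedTermGenes <- sort(resample(targetUnion, min(nCover, length(targetUnion))))
  plantedTermId <- sprintf("T_%s_PLANTED", pl$plantedCategory)

  ## spurious rows at the configured noise rate
  addNoise <- function(rows, gen) {
    extra <- floor(config@noise * length(rows))
    for (i in seq_len(extra)) rows[[length(rows) + 1L]] <- gen()
    rows
  }
  diseaseIds <- unique(vapply(pdRows, `[[`, "", 1L))
  pdRows <- addNoise(pdRows, function()
    c(resample(diseaseIds, 1L), resample(leaves, 1L)))
  dgRows <- addNoise(dgRows, function()
    c(resample(diseaseIds, 1L), resample(genePool, 1L)))

  ## --- GMT catalogs -----------------------------------------------------
  gmt <- list()
  for (cat in names(config@nFunctionalTerms)) {
    lines <- character(0)
    for (i in seq_len(config@nFunctionalTerms[[cat]])) {
      sz <- sample(5:12, 1L)
      gs <- sort(resample(genePool, sz))
      lines <- c(lines, paste(c(sprintf("T_%s_%03d", cat, i),
                                sprintf("random %s term %03d", cat, i), gs),
                              collapse = "\t"))
    }
    if (cat == pl$plantedCategory)
      lines <- c(lines, paste(c(plantedTermId, "planted shared process",
                                plantedTermGenes), collapse = "\t"))
    gmt[[cat]] <- paste(c(lines, ""), collapse = "\n")
  }

  ## --- interaction network ---------------------------------------------
  hub <- genePool[[config@nGenesBackground]]
  netRows <- lapply(plantedGenes, function(g) c(g, hub))
  nRandom <- max(0L, round(config@networkDegree * 30 / 2))
  netNodes <- genePool[seq_len(min(60L, length(genePool)))]
  for (i in seq_len(nRandom)) {
    pair <- resample(netNodes, 2L)
    netRows[[length(netRows) + 1L]] <- sort(pair)
  }

  ## --- blind set ---------------------------------------------------------
  blindRows <- list()
  blindTruth <- list()
  for (i in seq_len(config@nBlindDiseases)) {
    d <- sprintf("ORPHA:7%05d", i)
    np <- min(length(targets), sample(2:3, 1L))
    phen <- sort(resample(targets, np))
    truth <- sort(resample(plantedGenes, sample(1:2, 1L)))
    blindRows[[i]] <- c(d, paste(phen, collapse = ";"),
                        paste(truth, collapse = ";"))
    blindTruth[[i]] <- list(disease_id = d, phenotypes = phen,
                            truth_genes = truth)
  }

  tsv <- function(header, rows) {
    paste(c(paste(header, collapse = "\t"),
            vapply(rows, paste, "", collapse = "\t"), ""), collapse = "\n")
  }
  new("FixtureBundle",
      oboText = paste(c(oboLines, ""), collapse = "\n"),
      phenotypeDiseaseTsv = tsv(c("disease_id", "phenotype_id"), pdRows),
      diseaseGeneTsv = tsv(c("disease_id", "gene_symbol"), dgRows),
      gmt = gmt,
      networkTsv = tsv(c("gene1", "gene2"), netRows),
      blindSetTsv = tsv(c("disease_id", "phenotype_ids", "gene_symbols"),
                        blindRows),
      truth = list(
        seed = config@seed,
        target_phenotypes = targets,
        planted_genes = plantedGenes,
        planted_term = list(category = pl$plantedCategory,
                            term_id = plantedTermId),
        blind = blindTruth))
}

#' Write a fixture bundle to disk
#'
#' Emits `phenotypes.obo`, `phenotype_disease.tsv`, `disease_gene.tsv`,
#' one `<CATEGORY>.gmt` per catalog, `network.tsv`, `blind_set.tsv` and
#' `truth.json` under `dir`.
#'
#' @param bundle a [FixtureBundle-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeFixture <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeChar2 <- function(text, f) {
    con <- file(file.path(dir, f), "wb")
    on.exit(close(con))
    writeBin(charToRaw(text), con)
  }
  writeChar2(bundle@oboText, "phenotypes.obo")
  writeChar2(bundle@phenotypeDiseaseTsv, "phenotype_disease.tsv")
  writeChar2(bundle@diseaseGeneTsv, "disease_gene.tsv")
  for (cat in names(bundle@gmt))
    writeChar2(bundle@gmt[[cat]], paste0(cat, ".gmt"))
  writeChar2(bundle@networkTsv, "network.tsv")
  writeChar2(bundle@blindSetTsv, "blind_set.tsv")
  writeCanonicalJSON(bundle@truth, file.path(dir, "truth.json"))
  invisible(dir)
}

#' Check pipeline reports against the planted truth
#'
#' Verifies that every planted gene appears in the shared genes of the
#' target-phenotype intersection, that the planted term is among the
#' shared enriched terms, and (when metrics are supplied) that every
#' blind disease was recovered.
#'
#' @param bundle the [FixtureBundle-class] the reports were produced from.
#' @param report an [IntersectionReport-class] over the bundle's target
#'   phenotypes.
#' @param metrics optional [RecoveryMetrics-class] from the bundle's blind
#'   set.
#' @return list with elements `pass` (logical) and `diffs` (character
#'   vector naming every unmet truth entry; empty when `pass`).
#' @export
verifyTruth <- function(bundle, report, metrics = NULL) {
  truth <- bundle@truth
  if (!setequal(report@query, truth$target_phenotypes))
    plUsageError("report query does not match the bundle's target phenotypes")
  diffs <- character(0)
  got <- names(sharedGenes(report))
  for (g in truth$planted_genes)
    if (!g %in% got)
      diffs <- c(diffs, sprintf("planted gene %s absent from shared genes", g))
  tt <- sharedTerms(report)
  hit <- tt$term_id == truth$planted_term$term_id &
    tt$category == truth$planted_term$category
  if (!any(hit))
    diffs <- c(diffs, sprintf("planted term %s/%s absent from shared terms",
                              truth$planted_term$category,
                              truth$planted_term$term_id))
  if (!is.null(metrics)) {
    pd <- metrics@perDisease
    for (b in truth$blind) {
      row <- pd[pd$disease_id == b$disease_id, , drop = FALSE]
      if (nrow(row) == 0L)
        plUsageError("blind disease %s missing from metrics: mismatched bundle/report",
                     b$disease_id)
      if (!row$recovered)
        diffs <- c(diffs, sprintf("blind disease %s not recovered",
                                  b$disease_id))
    }
  }
  list(pass = length(diffs) == 0L, diffs = diffs)
}

#' @describeIn FixtureBundle-class compact summary.
#' @param object a `FixtureBundle`.
#' @export
setMethod("show", "FixtureBundle", function(object) {
  cat(sprintf(
    "FixtureBundle (seed %d): %d catalogs, %d target phenotypes, %d planted genes, %d blind diseases\n",
    object@truth$seed, length(object@gmt),
    length(object@truth$target_phenotypes),
    length(object@truth$planted_genes), length(object@truth$blind)))
  invisible(NULL)
})
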