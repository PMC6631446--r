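# A small hand-built knowledge base with the three-phenotype topology of
# the obesity/diabetes/ovarian-cyst workflow: one gene shared by all three
# query phenotypes, others shared only pairwise.
threePhenotypeContext <- function() {
  dag <- readOBO(oboText(
    oboStanza("XX:0000001", "root"),
    oboStanza("XX:0000010", "Obesity", "XX:0000001",
              synonyms = "increased body weight"),
    oboStanza("XX:0000011", "Diabetes mellitus type II", "XX:0000001"),
    oboStanza("XX:0000012", "Ovarian cyst", "XX:0000001")))
  pdTsv <- paste(c("disease_id\tphenotype_id",
                   "OMIM:1\tXX:0000010", "OMIM:2\tXX:0000010",
                   "OMIM:2\tXX:0000011", "OMIM:3\tXX:0000011",
                   "OMIM:4\tXX:0000012", "OMIM:5\tXX:0000010",
                   "OMIM:5\tXX:0000011", "OMIM:6\tXX:0000012"),
                 collapse = "\n")
  # GALL reaches all three phenotypes; GAB only the first two; GBC the
  # last two; GA only the first.
  dgTsv <- paste(c("disease_id\tgene_symbol",
                   "OMIM:1\tGALL", "OMIM:2\tGAB", "OMIM:3\tGALL",
                   "OMIM:3\tGBC", "OMIM:4\tGALL", "OMIM:4\tGBC",
                   "OMIM:5\tGAB2", "OMIM:1\tGA", "OMIM:6\tGQ"),
                 collapse = "\n")
  pd <- loadPhenotypeDisease(pdTsv, dag, propagate = FALSE)
  dg <- loadDiseaseGene(dgTsv)
  index <- collapseDiseaseLayer(pd, dg)
  cat <- functionalCatalog("GO_BP", list(
    SHARED = c("GALL", "GAB", "GBC", "GA", "GAB2", "GQ"),
    OTHER = sprintf("GX%02d", 1:20)))
  list(dag = dag, pd = pd, dg = dg, index = index, catalogs = list(cat))
}

# canonical comparable form (slots only)
reportAsListForTest <- function(rep) {
  list(rep@query, rep@sharedDiseases, rep@sharedGenes, rep@sharedTerms,
       lapply(rep@analyses, function(a)
         list(a@phenotype, a@diseases, a@genes, a@provenance,
              a@enrichments, a@note)))
}

test_that("phenotype resolution handles ids, names, synonyms and misses", {
  ctx <- threePhenotypeContext()
  q <- resolvePhenotypes(c("XX:0000010", "ovarian", "body weight",
                           "nose twitch", "XX:0099999"), ctx$dag)
  expect_identical(q@resolved[["XX:0000010"]], "XX:0000010")
  expect_identical(q@resolved[["ovarian"]], "XX:0000012")
  expect_identical(q@resolved[["body weight"]], "XX:0000010")  # synonym
  expect_setequal(q@unresolved, c("nose twitch", "XX:0099999"))
  expect_setequal(q@selected, c("XX:0000010", "XX:0000012"))

  # ambiguous fragments return all candidates for user selection
  q <- resolvePhenotypes("o", ctx$dag)
  expect_gte(length(q@resolved[["o"]]), 2L)

  # obsolete terms never resolve
  dag <- readOBO(oboText(oboStanza("XX:0000001", "alive"),
                         oboStanza("XX:0000002", "gone", obsolete = TRUE)))
  q <- resolvePhenotypes(c("gone", "XX:0000002"), dag)
  expect_setequal(q@unresolved, c("gone", "XX:0000002"))
})

test_that("general analysis assembles diseases, genes and enrichment", {
  ctx <- threePhenotypeContext()
  ga <- generalAnalysis("XX:0000010", ctx$index, ctx$pd, ctx$catalogs,
                        alpha = 1)
  expect_setequal(ga@diseases, c("OMIM:1", "OMIM:2", "OMIM:5"))
  expect_setequal(ga@genes, c("GALL", "GAB", "GAB2", "GA"))
  expect_identical(ga@provenance[["GALL"]], "OMIM:1")
  hits <- unlist(strsplit(ga@enrichments$GO_BP$hit_genes, ";"))
  expect_true(all(hits %in% ga@genes))

  # single-gene phenotype: enrichment skipped with a note
  dag <- readOBO(chainOBO())
  pd <- loadPhenotypeDisease("disease_id\tphenotype_id\nOMIM:1\tXX:0000003\n",
                             dag, propagate = FALSE)
  dg <- loadDiseaseGene("disease_id\tgene_symbol\nOMIM:1\tG1\n")
  idx <- collapseDiseaseLayer(pd, dg)
  ga <- generalAnalysis("XX:0000003", idx, pd, ctx$catalogs)
  expect_length(ga@enrichments, 0L)
  expect_match(ga@note, "below minimum gene count")

  # phenotype with no diseases at all
  pd2 <- new("PhenotypeDiseaseMap",
             assoc = list(`XX:0000002` = character(0)),
             propagated = FALSE, skipped = 0L)
  idx2 <- collapseDiseaseLayer(pd2, dg)
  ga <- generalAnalysis("XX:0000002", idx2, pd2, ctx$catalogs)
  expect_length(ga@diseases, 0L)
  expect_match(ga@note, "no molecular information")
  expect_error(generalAnalysis("XX:0000099", idx, pd, list()),
               class = "plLookupError")
})

test_that("three-phenotype intersection separates full from pairwise sharing", {
  ctx <- threePhenotypeContext()
  rep <- intersectPhenotypes(c("XX:0000010", "XX:0000011", "XX:0000012"),
                             ctx$index, ctx$pd, ctx$catalogs, alpha = 0.05)
  g <- sharedGenes(rep)
  # exactly one gene carried by all three
  expect_identical(names(sharedGenes(rep, fullOnly = TRUE)), "GALL")
  expect_identical(g[["GALL"]],
                   c("XX:0000010", "XX:0000011", "XX:0000012"))
  # pairwise-shared genes carry exactly their two phenotypes
  expect_identical(g[["GAB"]], c("XX:0000010", "XX:0000011"))
  expect_identical(g[["GBC"]], c("XX:0000011", "XX:0000012"))
  expect_false("GA" %in% names(g))  # single-phenotype gene is not shared

  # diseases shared by >= 2 phenotypes, full intersection flagged separately
  d <- sharedDiseases(rep)
  expect_identical(d[["OMIM:2"]], c("XX:0000010", "XX:0000011"))
  expect_length(sharedDiseases(rep, fullOnly = TRUE), 0L)

  tt <- sharedTerms(rep)
  expect_true("SHARED" %in% tt$term_id)
  expect_true(tt$full_intersection[tt$term_id == "SHARED"])
  expect_false("OTHER" %in% tt$term_id)
})

test_that("shared terms agree with each phenotype's own analysis", {
  ctx <- threePhenotypeContext()
  rep <- intersectPhenotypes(c("XX:0000010", "XX:0000011"), ctx$index,
                             ctx$pd, ctx$catalogs, alpha = 0.05)
  tt <- sharedTerms(rep)
  for (i in seq_len(nrow(tt))) {
    phen <- strsplit(tt$phenotypes[[i]], ";")[[1L]]
    ps <- as.numeric(strsplit(tt$p_corrected[[i]], ";")[[1L]])
    for (j in seq_along(phen)) {
      tab <- rep@analyses[[phen[[j]]]]@enrichments[[tt$category[[i]]]]
      row <- tab[tab$term_id == tt$term_id[[i]], ]
      expect_identical(nrow(row), 1L)
      expect_lte(row$p_bonferroni, rep@alpha)
      expect_equal(ps[[j]], row$p_bonferroni, tolerance = 1e-5)
    }
  }
})

test_that("intersection is symmetric and monotone under query growth", {
  ctx <- threePhenotypeContext()
  ab <- intersectPhenotypes(c("XX:0000010", "XX:0000011"), ctx$index,
                            ctx$pd, ctx$catalogs)
  ba <- intersectPhenotypes(c("XX:0000011", "XX:0000010"), ctx$index,
                            ctx$pd, ctx$catalogs)
  expect_identical(reportAsListForTest(ab), reportAsListForTest(ba))

  abc <- intersectPhenotypes(c("XX:0000010", "XX:0000011", "XX:0000012"),
                             ctx$index, ctx$pd, ctx$catalogs)
  # adding a phenotype never shrinks an existing item's carrying set
  for (gn in names(sharedGenes(ab)))
    expect_true(all(sharedGenes(ab)[[gn]] %in% sharedGenes(abc)[[gn]]))
  for (d in names(sharedDiseases(ab)))
    expect_true(all(sharedDiseases(ab)[[d]] %in% sharedDiseases(abc)[[d]]))
  # full-intersection items are exactly those carried by the whole query
  full <- sharedGenes(abc, fullOnly = TRUE)
  expect_true(all(lengths(full) == 3L))
})

test_that("degenerate queries are rejected or deduplicated", {
  ctx <- threePhenotypeContext()
  expect_error(intersectPhenotypes("XX:0000010", ctx$index, ctx$pd),
               class = "plUsageError")
  expect_warning(
    rep <- intersectPhenotypes(c("XX:0000010", "XX:0000010", "XX:0000011"),
                               ctx$index, ctx$pd),
    "duplicate")
  expect_identical(rep@query, c("XX:0000010", "XX:0000011"))
})

test_that("pairwise store materializes C(n,2) byte-stable reports", {
  ctx <- threePhenotypeContext()
  dir <- tempfile()
  phen <- c("XX:0000010", "XX:0000011", "XX:0000012")
  files <- precomputePairwise(phen, dir, ctx$index, ctx$pd, ctx$catalogs)
  expect_length(files, 3L)  # C(3, 2)
  expect_true(all(file.exists(files)))
  # round-trip: the stored file equals a fresh recomputation, byte for byte
  pair <- c("XX:0000010", "XX:0000012")
  fresh <- intersectPhenotypes(pair, ctx$index, ctx$pd, ctx$catalogs)
  f2 <- tempfile(fileext = ".json")
  writeIntersectionReport(fresh, f2)
  stored <- files[[paste(pair, collapse = "__")]]
  expect_identical(readLines(stored), readLines(f2))
})

test_that("report writers emit the TSV tables and JSON document", {
  ctx <- threePhenotypeContext()
  rep <- intersectPhenotypes(c("XX:0000010", "XX:0000011", "XX:0000012"),
                             ctx$index, ctx$pd, ctx$catalogs)
  prefix <- tempfile()
  paths <- writeIntersectionReport(rep, prefix)
  genes <- read.delim(paste0(prefix, "_genes.tsv"), stringsAsFactors = FALSE)
  expect_true("GALL" %in% genes$item)
  expect_true(genes$full_intersection[genes$item == "GALL"])
  jf <- tempfile(fileext = ".json")
  writeIntersectionReport(rep, jf)
  doc <- jsonlite::fromJSON(jf)
  expect_identical(doc$query, rep@query)
  expect_true("GALL" %in% names(doc$shared_genes))
})
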