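chainDag <- function() readOBO(chainOBO())

test_that("phenotype-disease loading propagates annotations to ancestors", {
  dag <- chainDag()
  tsv <- "disease_id\tphenotype_id\nOMIM:1\tXX:0000003\n"
  pd <- loadPhenotypeDisease(tsv, dag, propagate = TRUE)
  expect_identical(pd@assoc,
                   list(`XX:0000001` = "OMIM:1", `XX:0000002` = "OMIM:1",
                        `XX:0000003` = "OMIM:1"))
  pd <- loadPhenotypeDisease(tsv, dag, propagate = FALSE)
  expect_identical(pd@assoc, list(`XX:0000003` = "OMIM:1"))
})

test_that("HPOA dialect is accepted: NOT rows dropped, bare ids prefixed", {
  dag <- chainDag()
  tsv <- paste("#comment", "database_id\tdisease_name\tqualifier\thpo_id",
               "100\tsome disease\t\tXX:0000003",
               "200\tother disease\tNOT\tXX:0000002",
               sep = "\n")
  pd <- loadPhenotypeDisease(tsv, dag, propagate = FALSE)
  expect_identical(names(pd@assoc), "XX:0000003")
  expect_identical(pd@assoc[["XX:0000003"]], "OMIM:100")
})

test_that("unknown or obsolete phenotype rows are skipped and counted", {
  dag <- readOBO(oboText(oboStanza("XX:0000001", "root"),
                         oboStanza("XX:0000002", "dead", "XX:0000001",
                                   obsolete = TRUE)))
  tsv <- paste("disease_id\tphenotype_id", "OMIM:1\tXX:0000001",
               "OMIM:2\tXX:0000002", "OMIM:3\tXX:0000099", sep = "\n")
  expect_warning(pd <- loadPhenotypeDisease(tsv, dag), "skipped 2 rows")
  expect_identical(pd@skipped, 2L)
  expect_identical(names(pd@assoc), "XX:0000001")
})

test_that("table format errors are reported", {
  dag <- chainDag()
  expect_error(loadPhenotypeDisease("foo\tbar\n1\t2\n", dag),
               class = "plFormatError")
  expect_warning(pd <- loadPhenotypeDisease("", dag), "empty")
  expect_length(pd@assoc, 0L)
  expect_error(loadDiseaseGene("foo\tbar\n1\t2\n"), class = "plFormatError")
})

test_that("disease-gene loading collapses duplicates and uppercases", {
  tsv <- paste("disease_id\tgene_symbol", "OMIM:1\tG1", "OMIM:1\tG2",
               "OMIM:1\tG1", "OMIM:2\tg1", sep = "\n")
  dg <- loadDiseaseGene(tsv)
  expect_identical(dg@assoc, list(`OMIM:1` = c("G1", "G2"), `OMIM:2` = "G1"))
})

test_that("collapsing the disease layer joins maps with provenance", {
  dag <- readOBO(oboText(oboStanza("XX:0000001", "root"),
                         oboStanza("XX:0000002", "p", "XX:0000001"),
                         oboStanza("XX:0000003", "q", "XX:0000001")))
  pd <- loadPhenotypeDisease(paste(
    "disease_id\tphenotype_id", "OMIM:1\tXX:0000002", "OMIM:2\tXX:0000002",
    "OMIM:1\tXX:0000003", "OMIM:3\tXX:0000003", sep = "\n"),
    dag, propagate = FALSE)
  dg <- loadDiseaseGene(paste(
    "disease_id\tgene_symbol", "OMIM:1\tG1", "OMIM:1\tG2", "OMIM:2\tG2",
    "OMIM:2\tG3", sep = "\n"))
  idx <- collapseDiseaseLayer(pd, dg)
  expect_identical(phenotypeGenes(idx, "XX:0000002"), c("G1", "G2", "G3"))
  expect_identical(geneProvenance(idx, "XX:0000002", "G2"),
                   c("OMIM:1", "OMIM:2"))
  # OMIM:3 has no genes: phenotype q keeps OMIM:1's genes only
  expect_identical(phenotypeGenes(idx, "XX:0000003"), c("G1", "G2"))
  expect_error(geneProvenance(idx, "XX:0000002", "G9"),
               class = "plLookupError")
})

test_that("phenotypes whose diseases have no genes are kept and flagged", {
  dag <- chainDag()
  pd <- loadPhenotypeDisease("disease_id\tphenotype_id\nOMIM:9\tXX:0000003\n",
                             dag, propagate = FALSE)
  dg <- loadDiseaseGene("disease_id\tgene_symbol\nOMIM:1\tG1\n")
  idx <- collapseDiseaseLayer(pd, dg)
  expect_identical(phenotypeGenes(idx, "XX:0000003"), character(0))
  expect_identical(idx@noGeneInfo, "XX:0000003")
})

test_that("propagation is idempotent", {
  set.seed(19)
  for (rep in 1:10) {
    g <- randomDAG(15)
    dag <- readOBO(g$obo)
    inst <- randomInstance(nPheno = 6L, dag = dag)
    pd <- loadPhenotypeDisease(inst$pdTsv, dag, propagate = TRUE)
    again <- PhenoLink:::propagateAssoc(pd@assoc, dag)
    expect_identical(again, pd@assoc)
  }
})

test_that("collapse matches a brute-force triple loop on random instances", {
  set.seed(23)
  for (rep in 1:10) {
    inst <- randomInstance(nPheno = sample(3:8, 1L),
                           nDisease = sample(5:15, 1L),
                           nGene = sample(10:30, 1L))
    phen <- sprintf("PP:%07d", seq_len(20))
    # flat map: no DAG propagation involved in this check
    pdAssoc <- lapply(split(inst$pdPairs$disease_id, inst$pdPairs$phenotype_id),
                      function(d) sort(unique(d)))
    pd <- new("PhenotypeDiseaseMap", assoc = pdAssoc[order(names(pdAssoc))],
              propagated = FALSE, skipped = 0L)
    dg <- loadDiseaseGene(inst$dgTsv)
    idx <- collapseDiseaseLayer(pd, dg)
    for (p in names(pd@assoc)) {
      expected <- character(0)
      for (d in inst$dis) {
        for (gn in inst$gene) {
          hasPD <- any(inst$pdPairs$disease_id == d &
                         inst$pdPairs$phenotype_id == p)
          hasDG <- any(inst$dgPairs$disease_id == d &
                         inst$dgPairs$gene_symbol == gn)
          if (hasPD && hasDG) expected <- c(expected, gn)
        }
      }
      expect_identical(phenotypeGenes(idx, p), sort(unique(expected)))
    }
    # provenance completeness: every indexed pair is witnessed
    for (p in names(idx@genes)) {
      for (gn in idx@genes[[p]]) {
        wit <- geneProvenance(idx, p, gn)
        expect_gt(length(wit), 0L)
        expect_true(all(wit %in% pd@assoc[[p]]))
        expect_true(all(vapply(wit, function(d) gn %in% dg@assoc[[d]],
                               logical(1))))
      }
    }
  }
})

test_that("association stats report the leaf-per-disease histogram", {
  dag <- chainDag()
  pd <- loadPhenotypeDisease("disease_id\tphenotype_id\nOMIM:1\tXX:0000003\n",
                             dag)
  dg <- loadDiseaseGene("disease_id\tgene_symbol\nOMIM:1\tG1\n")
  idx <- collapseDiseaseLayer(pd, dg)
  st <- associationStats(pd, dg, idx, dag)
  expect_identical(st$leafPhenotypesPerDisease, c(`1` = 1L))
  expect_identical(st$maxLeafPhenotypes, 1L)

  # disease on 5 leaves -> histogram {5: 1}
  bundle <- generateFixture(fixtureConfig(seed = 5, nDiseases = 1L,
                                          phenotypesPerDisease = c(5L, 5L),
                                          nBlindDiseases = 1L,
                                          nTargetPhenotypes = 2L))
  ctx <- bundleContext(bundle)
  st <- associationStats(ctx$pd, ctx$dg, ctx$index, ctx$dag)
  expect_identical(unname(st$leafPhenotypesPerDisease[["5"]]), 1L)
  expect_identical(st$maxLeafPhenotypes, 5L)

  # histogram total equals the number of leaf-annotated diseases (recount)
  bundle <- generateFixture(fixtureConfig(seed = 17))
  ctx <- bundleContext(bundle)
  st <- associationStats(ctx$pd, ctx$dg, ctx$index, ctx$dag)
  leafDiseases <- unique(unlist(
    ctx$pd@assoc[intersect(names(ctx$pd@assoc), dagLeaves(ctx$dag))],
    use.names = FALSE))
  expect_identical(sum(st$leafPhenotypesPerDisease),
                   length(leafDiseases))
})

test_that("the collapsed index writes and re-reads as TSV", {
  dag <- chainDag()
  pd <- loadPhenotypeDisease("disease_id\tphenotype_id\nOMIM:1\tXX:0000003\n",
                             dag)
  dg <- loadDiseaseGene("disease_id\tgene_symbol\nOMIM:1\tG1\nOMIM:1\tG2\n")
  idx <- collapseDiseaseLayer(pd, dg)
  f <- tempfile(fileext = ".tsv")
  writeGeneIndex(idx, f)
  back <- read.delim(f, stringsAsFactors = FALSE)
  expect_identical(nrow(back), 6L)  # 3 phenotypes x 2 genes after propagation
  expect_setequal(unique(back$diseases), "OMIM:1")
})
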