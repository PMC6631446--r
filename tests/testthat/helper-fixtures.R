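# Shared test helpers: OBO text builders, random DAGs with an independent
# reachability oracle, random toy association instances, and an exact
# rational hypergeometric tail oracle.

oboStanza <- function(id, name = id, parents = character(0),
                      obsolete = FALSE, synonyms = character(0),
                      namespace = NULL) {
  c("[Term]", paste0("id: ", id), paste0("name: ", name),
    if (!is.null(namespace)) paste0("namespace: ", namespace),
    vapply(parents, function(p) paste0("is_a: ", p), ""),
    vapply(synonyms, function(s) sprintf('synonym: "%s" EXACT []', s), ""),
    if (obsolete) "is_obsolete: true", "")
}

oboText <- function(...) paste(c("format-version: 1.2", "", ...),
                               collapse = "\n")

# chain A <- B <- C (C is_a B is_a A)
chainOBO <- function() oboText(
  oboStanza("XX:0000001", "A"),
  oboStanza("XX:0000002", "B", "XX:0000001"),
  oboStanza("XX:0000003", "C", "XX:0000002"))

# diamond: A <- B, A <- C, B <- D, C <- D
diamondOBO <- function() oboText(
  oboStanza("XX:0000001", "A"),
  oboStanza("XX:0000002", "B", "XX:0000001"),
  oboStanza("XX:0000003", "C", "XX:0000001"),
  oboStanza("XX:0000004", "D", c("XX:0000002", "XX:0000003")))

# Random layered DAG: returns list(ids, parents (named list), obo text).
# Acyclic by construction (parents only from earlier ids).
randomDAG <- function(n, maxParents = 3L) {
  ids <- sprintf("RD:%07d", seq_len(n))
  parents <- list()
  parents[[ids[[1L]]]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    k <- sample(0:min(maxParents, i - 1L), 1L)
    parents[[ids[[i]]]] <- if (k > 0L) sort(sample(ids[seq_len(i - 1L)], k))
                           else character(0)
  }
  stanzas <- lapply(seq_len(n), function(i)
    oboStanza(ids[[i]], sprintf("node %d", i), parents[[ids[[i]]]]))
  list(ids = ids, parents = parents, obo = do.call(oboText, stanzas))
}

# Brute-force strict-ancestor sets by boolean matrix powers of the
# child -> parent adjacency matrix (transitive closure).
reachabilityOracle <- function(ids, parents) {
  n <- length(ids)
  A <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (id in ids) A[id, parents[[id]]] <- TRUE
  R <- A
  P <- A
  for (step in seq_len(n)) {
    P <- (P %*% A) > 0
    newR <- R | P
    if (identical(newR, R)) break
    R <- newR
  }
  lapply(stats::setNames(ids, ids), function(id) sort(colnames(R)[R[id, ]]))
}

# Random toy phenotype/disease/gene instance as raw TSV text plus the
# underlying relations for brute-force checks.
randomInstance <- function(nPheno = 8L, nDisease = 12L, nGene = 20L,
                           dag = NULL) {
  phen <- if (is.null(dag)) sprintf("PP:%07d", seq_len(nPheno))
          else sample(dag@terms$term_id[!dag@terms$obsolete], nPheno)
  dis <- sprintf("MIM:6%05d", seq_len(nDisease))
  gene <- sprintf("G%03d", seq_len(nGene))
  pdPairs <- unique(data.frame(
    disease_id = sample(dis, nDisease * 2L, replace = TRUE),
    phenotype_id = sample(phen, nDisease * 2L, replace = TRUE),
    stringsAsFactors = FALSE))
  dgPairs <- unique(data.frame(
    disease_id = sample(dis, nDisease * 2L, replace = TRUE),
    gene_symbol = sample(gene, nDisease * 2L, replace = TRUE),
    stringsAsFactors = FALSE))
  list(
    phen = phen, dis = dis, gene = gene,
    pdPairs = pdPairs, dgPairs = dgPairs,
    pdTsv = paste(c("disease_id\tphenotype_id",
                    paste(pdPairs$disease_id, pdPairs$phenotype_id,
                          sep = "\t"), ""), collapse = "\n"),
    dgTsv = paste(c("disease_id\tgene_symbol",
                    paste(dgPairs$disease_id, dgPairs$gene_symbol,
                          sep = "\t"), ""), collapse = "\n"))
}

# Exact rational hypergeometric upper-tail oracle, computed with Python's
# arbitrary-precision integers and Fraction (correctly rounded to double).
# Independent of the package's phyper-based implementation.
exactHyperTail <- function(k, K, n, N) {
  script <- '
import sys
from fractions import Fraction
from math import comb
for line in sys.stdin:
    line = line.strip()
    if not line:
        continue
    k, K, n, N = (int(x) for x in line.split(","))
    num = sum(comb(K, i) * comb(N - K, n - i)
              for i in range(k, min(K, n) + 1))
    p = Fraction(num, comb(N, n))
    print(repr(p.numerator / p.denominator))
'
  scriptFile <- tempfile(fileext = ".py")
  writeLines(script, scriptFile)
  inFile <- tempfile()
  writeLines(sprintf("%d,%d,%d,%d", k, K, n, N), inFile)
  out <- system2("python", scriptFile, stdout = TRUE, stdin = inFile)
  as.numeric(out)
}

# Small ready-made analysis context from a fixture bundle.
bundleContext <- function(bundle) {
  dag <- readOBO(bundle@oboText)
  pd <- suppressWarnings(loadPhenotypeDisease(bundle@phenotypeDiseaseTsv, dag))
  dg <- loadDiseaseGene(bundle@diseaseGeneTsv)
  index <- collapseDiseaseLayer(pd, dg)
  catalogs <- lapply(names(bundle@gmt), function(cat)
    readGMT(bundle@gmt[[cat]], cat))
  names(catalogs) <- names(bundle@gmt)
  list(dag = dag, pd = pd, dg = dg, index = index, catalogs = catalogs,
       network = readNetwork(bundle@networkTsv))
}
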