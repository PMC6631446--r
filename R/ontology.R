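## OBO parsing and DAG queries: ancestor/descendant closure, leaves,
## sub-ontology extraction, information content.

#' Parse an OBO-format ontology into a DAG
#'
#' Reads OBO 1.2-style `[Term]` stanzas carrying `id`, `name` and optional
#' `is_a`, `is_obsolete`, `namespace` and `synonym` lines. Unknown tags and
#' non-Term stanzas are ignored. Only `is_a` edges define the DAG; obsolete
#' terms are retained (for identifier resolution messages) but carry no
#' edges and are excluded from closure, leaf and search results.
#'
#' @param x path to an OBO file, or OBO text (a single string or a
#'   character vector of lines).
#' @return an [OntologyDAG-class].
#' @examples
#' dag <- readOBO(c("[Term]", "id: XX:0000001", "name: root",
#'                  "[Term]", "id: XX:0000002", "name: child",
#'                  "is_a: XX:0000001 ! root"))
#' dagLeaves(dag)
#' @export
readOBO <- function(x) {
  lines <- readInput(x)
  lines <- trimws(lines)

  stanzaStarts <- grep("^\\[.*\\]$", lines)
  termStarts <- which(lines == "[Term]")
  if (length(termStarts) == 0L)
    plLoadError("no [Term] stanzas found in OBO input")

  ids <- character(); nms <- character(); ns <- character(); obs <- logical()
  parents <- list(); synonyms <- list()

  bounds <- c(stanzaStarts, length(lines) + 1L)
  for (s in termStarts) {
    endIdx <- min(bounds[bounds > s]) - 1L
    body <- lines[seq.int(s + 1L, length.out = max(0L, endIdx - s))]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    tagMatch <- regmatches(body, regexec("^([A-Za-z_]+):\\s*(.*)$", body))
    tags <- vapply(tagMatch, function(m) if (length(m)) m[[2L]] else "", "")
    vals <- vapply(tagMatch, function(m) if (length(m)) m[[3L]] else "", "")

    id <- vals[tags == "id"][1L]
    if (is.na(id) || !nzchar(id)) plLoadError("[Term] stanza without an id")
    if (id %in% ids) plLoadError("duplicate term id '%s'", id)

    isA <- vals[tags == "is_a"]
    isA <- unique(trimws(sub("!.*$", "", isA)))  # strip trailing comments
    isA <- isA[nzchar(isA)]
    if (id %in% isA) plLoadError("self is_a loop at '%s'", id)

    isObs <- any(tags == "is_obsolete" & grepl("^true", vals))
    syn <- vals[tags == "synonym"]
    synText <- regmatches(syn, regexec('"([^"]*)"', syn))
    syn <- vapply(synText, function(m) if (length(m) == 2L) m[[2L]] else "", "")
    syn <- syn[nzchar(syn)]

    ids <- c(ids, id)
    nms <- c(nms, if (any(tags == "name")) vals[tags == "name"][1L] else "")
    ns <- c(ns, if (any(tags == "namespace")) vals[tags == "namespace"][1L]
              else NA_character_)
    obs <- c(obs, isObs)
    parents[[id]] <- if (isObs) character(0) else isA
    synonyms[[id]] <- syn
  }

  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling))
    plLoadError("is_a target '%s' is not defined in the ontology",
                dangling[[1L]])

  children <- buildChildren(ids, parents)
  checkAcyclic(ids, parents, children)

  new("OntologyDAG",
      terms = data.frame(term_id = ids, name = nms, namespace = ns,
                         obsolete = obs, stringsAsFactors = FALSE),
      parents = parents, children = children, synonyms = synonyms)
}

buildChildren <- function(ids, parents) {
  children <- stats::setNames(vector("list", length(ids)), ids)
  for (id in ids) children[[id]] <- character(0)
  for (id in ids) for (p in parents[[id]])
    children[[p]] <- c(children[[p]], id)
  children
}

## Kahn's algorithm over the child->parent edges; names one edge on a cycle.
checkAcyclic <- function(ids, parents, children) {
  indeg <- lengths(children)
  queue <- ids[indeg[ids] == 0L]
  seen <- character(0)
  while (length(queue)) {
    u <- queue[[1L]]; queue <- queue[-1L]; seen <- c(seen, u)
    for (p in parents[[u]]) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(seen) != length(ids)) {
    left <- setdiff(ids, seen)
    ## every node of the actual cycle has a not-yet-removed parent
    u <- left[[which(vapply(left, function(v)
      length(intersect(parents[[v]], left)) > 0L, logical(1)))[[1L]]]]
    p <- intersect(parents[[u]], left)[[1L]]
    plLoadError("cycle detected in is_a relation, involving edge '%s' is_a '%s'",
                u, p)
  }
  invisible(TRUE)
}

checkTerm <- function(dag, termId, allowObsolete = FALSE) {
  idx <- match(termId, dag@terms$term_id)
  if (is.na(idx)) plLookupError("unknown term id '%s'", termId)
  if (!allowObsolete && dag@terms$obsolete[idx])
    plLookupError("term '%s' is obsolete", termId)
  invisible(idx)
}

#' Strict ancestors of a term
#'
#' All terms reachable from `termId` by following `is_a` edges upward,
#' excluding the term itself and deduplicated across diamond paths.
#'
#' @param dag an [OntologyDAG-class].
#' @param termId a non-obsolete term id.
#' @return character vector of ancestor term ids (sorted).
#' @export
termAncestors <- function(dag, termId) {
  checkTerm(dag, termId)
  bfsClosure(dag@parents, termId)
}

#' Strict descendants of a term
#'
#' @inheritParams termAncestors
#' @return character vector of descendant term ids (sorted).
#' @export
termDescendants <- function(dag, termId) {
  checkTerm(dag, termId)
  bfsClosure(dag@children, termId)
}

bfsClosure <- function(adj, start) {
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(adj[frontier], use.names = FALSE))
  }
  sort(seen)
}

#' Leaf terms of the DAG
#'
#' Non-obsolete terms without children — the most specific annotation
#' level of the ontology.
#'
#' @param dag an [OntologyDAG-class].
#' @return sorted character vector of leaf term ids.
#' @export
dagLeaves <- function(dag) {
  alive <- dag@terms$term_id[!dag@terms$obsolete]
  sort(alive[lengths(dag@children[alive]) == 0L])
}

#' Root terms of the DAG
#'
#' @param dag an [OntologyDAG-class].
#' @return sorted character vector of non-obsolete term ids with no parents.
#' @export
dagRoots <- function(dag) {
  alive <- dag@terms$term_id[!dag@terms$obsolete]
  sort(alive[lengths(dag@parents[alive]) == 0L])
}

#' Number of terms in the DAG
#' @param dag an [OntologyDAG-class].
#' @param includeObsolete count obsolete terms too?
#' @export
nTerms <- function(dag, includeObsolete = TRUE) {
  if (includeObsolete) nrow(dag@terms) else sum(!dag@terms$obsolete)
}

#' Extract the sub-ontology rooted at a term
#'
#' Induced DAG of `rootId` and all its descendants; parent links pointing
#' outside the subtree are dropped, making `rootId` a root of the result.
#'
#' @param dag an [OntologyDAG-class].
#' @param rootId an existing term id.
#' @return an [OntologyDAG-class].
#' @export
subOntology <- function(dag, rootId) {
  checkTerm(dag, rootId, allowObsolete = TRUE)
  keep <- c(rootId, if (!dag@terms$obsolete[match(rootId, dag@terms$term_id)])
                      termDescendants(dag, rootId))
  tm <- dag@terms[dag@terms$term_id %in% keep, , drop = FALSE]
  rownames(tm) <- NULL
  parents <- lapply(tm$term_id, function(id)
    intersect(dag@parents[[id]], keep))
  names(parents) <- tm$term_id
  new("OntologyDAG", terms = tm, parents = parents,
      children = buildChildren(tm$term_id, parents),
      synonyms = dag@synonyms[tm$term_id])
}

#' Information content of an annotation term
#'
#' Specificity score of a term given the number of genes annotated with it
#' (`nTerm`) and the number of genes annotated anywhere in the catalog or
#' ontology (`nRoot`):
#' \deqn{IC = -\log_2(N_{term} / N_{root})}
#' The lower bound is zero (term annotating the whole universe); high
#' values mean few genes carry the term, i.e. a highly informative
#' annotation.
#'
#' @param nTerm positive count of genes annotated to the term.
#' @param nRoot positive count of genes annotated in the whole catalog;
#'   must be `>= nTerm`. Both arguments are vectorized.
#' @return information content in bits.
#' @examples
#' informationContent(3, 96)   # 5 bits
#' @export
informationContent <- function(nTerm, nRoot) {
  if (length(nTerm) != length(nRoot))
    nRoot <- rep_len(nRoot, length(nTerm))
  if (any(nTerm <= 0) || any(nRoot <= 0))
    plDomainError("gene counts must be positive")
  if (any(nTerm > nRoot))
    plDomainError("nTerm cannot exceed nRoot")
  -log2(nTerm / nRoot)
}

#' @describeIn OntologyDAG-class compact summary.
#' @param object an `OntologyDAG`.
#' @export
setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf(
    "OntologyDAG: %d terms (%d obsolete), %d roots, %d leaves\n",
    nrow(object@terms), sum(object@terms$obsolete),
    length(dagRoots(object)), length(dagLeaves(object))))
  invisible(NULL)
})
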