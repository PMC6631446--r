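---
title: "Linking co-occurring phenotypes to shared genes and functions"
author: "PhenoLink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking co-occurring phenotypes to shared genes and functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhenoLink)
```

## The problem

Patients frequently present several phenotypes at once, and a parsimonious
explanation tries to reconcile that multiplicity with the perturbation of
one or a few biological functions. Resources that annotate diseases with
phenotype terms (a phenotype ontology organized as a DAG, or flat clinical
categorizations) and databases that link diseases to causative genes
together form a tripartite phenotype–disease–gene graph. Collapsing the
middle (disease) layer yields direct phenotype→gene associations; gene-set
over-representation analysis then attaches biological processes and
pathways to each phenotype; and intersecting several phenotypes surfaces
the diseases, genes and functions they share — candidate molecular
explanations for their co-occurrence.

PhenoLink implements that pipeline end to end: OBO parsing and DAG
queries, ancestor propagation of disease annotations, disease-layer
collapse with provenance, Fisher-exact enrichment with Bonferroni
correction and information-content scoring, multi-phenotype intersection
reports, a blind-evaluation harness for causative-gene recovery, and a
seeded synthetic-data generator so that the whole machinery is testable
offline.

## The model, step by step

**Ontology and propagation.** Phenotype terms form a directed acyclic
graph whose edges are `is_a` relations; a *leaf* is a term with no
children and carries the most specific annotation. When a disease is
annotated to a phenotype, the annotation is extended to every ancestor of
that term, so a general term accumulates the diseases of its whole
subtree. Multi-parent "diamonds" are handled as set unions — path
multiplicity is irrelevant to propagation. Only `is_a` edges define the
graph; other relation types, common in richer ontologies, are ignored
because phenotype hierarchies are `is_a`-based. Obsolete terms are kept
for name/ID resolution (so a query can be told "this term is retired")
but carry no edges and never appear in closures, leaves or search
results. Flat categorizations (clinical-synopsis style) are the
degenerate case: a one-level ontology loaded with `propagate = FALSE`.

**Collapse.** With `pd` the phenotype→disease map after propagation and
`dg` the disease→gene map, the index is

$$\mathrm{genes}(p) \;=\; \bigcup_{d \,\in\, \mathrm{pd}(p)} \mathrm{dg}(d),$$

and every `(p, g)` pair records the mediating diseases. Phenotypes whose
diseases have no known genes are kept with empty sets and flagged, so a
query can report "no molecular information" instead of silently dropping
a term. Gene symbols are uppercased on load; alias resolution is out of
scope and symbols are compared literally.

**Enrichment.** For a query gene set of size $n$ drawn from a catalog
background of $N$ genes, a term annotating $K$ genes with overlap $k$ is
scored by the one-sided Fisher exact (hypergeometric upper-tail)
p-value $P(X \ge k)$, computed with `stats::phyper`. Raw p-values are
Bonferroni-corrected with $m$ = the number of terms tested in that
catalog (terms with zero overlap still count: the conservative reading of
the test family), and results with corrected $p \le \alpha$ are kept.
Each term also carries its information content

$$IC = -\log_2\!\left(\frac{N_{term}}{N_{root}}\right)\ \text{(bits)},$$

where $N_{term}$ is the number of genes annotated with the term and
$N_{root}$ the number of genes annotated anywhere in that catalog. IC is
zero when a term annotates the whole universe and grows as the term
becomes more specific. Each catalog (GO BP/MF/CC, KEGG, Reactome, ...)
keeps its own background universe, defaulting to the union of its term
gene sets; a custom universe may be supplied. IC uses the direct per-term
gene counts by default; for catalogs that carry their own term DAG, a
flag switches to ancestor-propagated counts.

**Network modules.** An optional mode expands each term's gene set with
connector genes lying on shortest interaction-network paths of length at
most `maxConnectorPath` between two term genes, then tests the query
against the expanded module restricted to the background. This is a
deliberately simple stand-in for full network-based enrichment methods
that build function-specific modules over an interactome: it reproduces
the idea (un-annotated genes bridging annotated ones join the module)
without that machinery. Two consequences are documented rather than
hidden: with the default cap of 1 a "path" is a direct edge and has no
intermediate vertex, so the default expansion is a no-op and the mode
equals classic ORA; connectors first appear at a cap of 2. And the test
is applied to the original query against module-expanded *term* sets —
whether the query side should also be expanded is left to the methods
that define such modules; we chose the term side and state it.

**Intersection.** A query of $\ge 2$ resolved phenotypes runs the
general analysis per phenotype, then reports every disease, gene and
enriched term carried by **at least two** of them, flagging separately
the items carried by **all** (the full intersection). "Carried", for a
term, means enriched at corrected $p \le \alpha$ within that phenotype's
own test family — each phenotype keeps its own Bonferroni correction, so
a term may be shared with very different per-phenotype p-values. Shared
terms are sorted by number of carrying phenotypes, then maximum IC
(more specific first), then term id; all orderings in the package are
total, so reports are deterministic and symmetric in the query order.

**Name resolution.** Inputs that look like accessions (`PREFIX:digits`)
resolve by exact id; anything else matches case-insensitively as a
literal substring of names and synonyms of non-obsolete terms. All
candidate matches are returned (ambiguity is the user's call), and
inputs with no match are reported, never fatal. No fuzzy matching.

**Blind evaluation.** A held-out disease with $\ge 2$ phenotype terms
and known causative genes is evaluated by intersecting its phenotypes
and retrieving the shared-gene list (carrying count $\ge 2$ by default;
a strict-all flag requires sharing across every phenotype, and a
widen-to-union flag is available for sensitivity analysis). The disease
counts as recovered when at least one truth gene is retrieved;
gene-level recovery pools (disease, gene) truth pairs across the set.
Diseases already present in the knowledge base are excluded on load, as
are diseases with fewer than two phenotypes.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance threshold on Bonferroni-corrected p |
| minimum query genes | 2 | enrichment requires two or more genes |
| `mode` | `standard` | `network` enables module expansion |
| `maxConnectorPath` | 1 | longest shortest-path between term genes admitting connectors |
| `propagate` | `TRUE` | extend disease annotations to DAG ancestors |
| `icPropagated` | `FALSE` | IC on propagated rather than direct counts |
| `strictAll` / `widenToUnion` | `FALSE` | blind-set retrieval variants |

The 0.05 threshold and the two-gene minimum are the conventional values
for this kind of over-representation pipeline and are surfaced as
configuration everywhere (functions and CLI flags).

## What the synthetic generator emulates

`fixtureConfig()` / `generateFixture()` produce a complete input bundle:
a layered random DAG (acyclic by construction: parents are only sampled
from earlier layers) of 10 internal terms and 16 leaves plus one obsolete
term; 12 background diseases annotated to 2–5 leaves each (echoing the
empirical pattern that most diseases annotate several phenotypes) and
1–3 genes from a 120-gene pool; GMT catalogs (15 GO-BP-like and 8
KEGG-like random terms of 5–12 genes); an interaction network joining
the planted genes through a hub connector plus random edges; and a
4-disease blind set. The planted signal is one term that covers the
target phenotypes' collapsed gene sets at the configured fraction
(default 1.0) and 6 planted genes shared by all 3 target phenotypes via
one dedicated disease each. The spurious-row `noise` dial appends random
association rows *after* the planted term is fixed, so noise can only
dilute the signal. The same configuration yields a byte-identical bundle;
the generator restores the caller's RNG state.

These toy bundles are deliberately unrealistic in several ways: gene
symbols and term names are synthetic, term sizes are uniform rather than
scale-free, the network is not a real interactome, and the catalogs have
no internal DAG. Passing tests therefore demonstrate the correctness of
the machinery (propagation, collapse, exact test, ranking, sharing
logic, recovery accounting) — not that any particular biological
database will yield signals of comparable strength. Quantities derived
from specific database snapshots (coverage percentages, real recovery
rates) are properties of those snapshots and are not reproduced here.

## Numerical and design choices

- The exact test is one-sided (over-representation); p-values come from
  `phyper(k - 1, K, N - K, n, lower.tail = FALSE)`. Unit and acceptance
  tests compare against an exact rational tail sum at relative error
  below $10^{-12}$.
- Bonferroni is $\min(1, p \cdot m)$, never below the raw p-value; the
  family is the catalog actually tested for that query.
- Ties in enrichment ranking break by higher IC, then lexicographic term
  id; shared-term ordering breaks ties the same way. Every output table
  and JSON document has a canonical ordering, which is what makes the
  pairwise store and CLI reruns byte-identical.
- Degenerate inputs are first-class: empty association tables load with
  a warning; phenotypes with zero genes are kept and flagged; queries
  below two genes are refused with the reason; query genes outside a
  catalog's universe are dropped with a warning, and if fewer than two
  remain that catalog simply contributes no results.
- Disease identifiers are namespaced strings; bare numeric ids are
  prefixed (`OMIM:` by default, configurable). HPOA-style rows with the
  `NOT` qualifier are negative assertions and are excluded.
- Where an upstream convention was genuinely open we decided and
  documented: IC defaults to direct catalog counts (propagated counts
  available by flag); flat clinical categorizations are treated as a
  single-level ontology without propagation; blind-set sharing defaults
  to carrying count $\ge 2$ with a strict-all option; pairwise
  intersections intersect per-phenotype enrichments rather than
  re-running enrichment on union gene sets.

## Problem sizes used in the test-suite and acceptance runs

Property tests use random DAGs up to 50 nodes (ancestor closure against a
matrix-power reachability oracle), 500 random 2×2 tables with $N \le 60$
(exact rational oracle), 50 random collapse instances against a triple
loop, and 100 seeded generator replicates for planted-signal recovery;
the acceptance script reruns the full pipeline on 100 seeded bundles.
These sizes were chosen so the whole suite exercises every code path in
well under a minute per property while remaining statistically
meaningful.

## Known limitations

- No identifier liftover (gene aliases, cross-vocabulary disease
  mappings); inputs are matched literally after case normalization.
- The network-module mode is a documented simplification, not a
  reimplementation of any published module-construction algorithm.
- Only Bonferroni is offered (no FDR), matching the upstream convention
  this pipeline follows.
- Substring-based name resolution can over-match short fragments; that
  is intentional (candidate lists for user selection), not a defect.

## A minimal session

```{r example}
bundle <- generateFixture(fixtureConfig(seed = 7))
dag <- readOBO(bundle@oboText)
pd <- loadPhenotypeDisease(bundle@phenotypeDiseaseTsv, dag)
dg <- loadDiseaseGene(bundle@diseaseGeneTsv)
index <- collapseDiseaseLayer(pd, dg)
catalogs <- lapply(names(bundle@gmt), function(cat)
  readGMT(bundle@gmt[[cat]], cat))

report <- intersectPhenotypes(bundle@truth$target_phenotypes,
                              index, pd, catalogs)
report
head(sharedTerms(report))
verifyTruth(bundle, report)$pass
```
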