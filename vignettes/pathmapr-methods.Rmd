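---
title: "Methods: cross-database pathway comparison, enrichment and mapping curation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-database pathway comparison, enrichment and mapping curation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmapr)
```

## The gene-set abstraction

`pathmapr` treats a pathway purely as a named, finite set of gene symbols
attached to one resource — the projection that every pathway database can
export (GMT files) and the only representation under which KEGG, Reactome
and WikiPathways content is directly commensurable. Topology, reactions
and metabolites are deliberately out of scope: every statistic in the
package is a function of gene sets, names and resource labels.

Gene symbols are HGNC-style plain tokens. The only normalization applied
is whitespace stripping and uppercasing (GMT exports vary in case); no
identifier-mapping service is consulted, so symbols pass through
otherwise unmodified. This keeps the package self-contained, at the cost
that unreconciled source vocabularies (e.g. Entrez ids mixed into a GMT)
will simply fail to overlap.

## Similarity metrics

**Content similarity** is the Szymkiewicz–Simpson overlap coefficient

$$S(X, Y) = \frac{|X \cap Y|}{\min(|X|, |Y|)},$$

chosen over Jaccard or Sørensen–Dice because pathway gene sets vary
widely in size and because $S = 1$ exactly when one set contains the
other — the signal that flags candidate hierarchical (`isPartOf`)
relationships. Both alternatives are available (`jaccard_index()`,
`dice_coefficient()`); $S$ dominates Jaccard pointwise, which the test
suite asserts on random pairs. $S$ is undefined when either set is empty;
the package returns 0 with a classed warning, on the view that an empty
pathway carries no evidence of similarity either way.

**Lexical similarity** between pathway names is
$1 - d(a, b) / \max(|a|, |b|)$, where $d$ is the Levenshtein edit
distance. The edit distance itself fixes no normalization, so the choice
of denominator (the longer name) is ours: it bounds the score to
$[0, 1]$ and is the standard convention in record linkage. Names are
compared case-insensitively after collapsing runs of whitespace; this
may rank near-ties differently from a case-sensitive comparison, which
we accept for robustness across databases' capitalization habits.

## Enrichment

`fisher_enrichment()` tests each pathway for over-representation of a
query gene list with the one-sided (greater) Fisher exact test: the
p-value is the hypergeometric upper tail $P(X \ge x)$ with
$X \sim \mathrm{Hypergeom}(N, K, n)$ for universe size $N$, pathway size
$K$, query size $n$ and overlap $x$. Only over-representation is tested
— "enrichment" has no meaningful depletion direction at typical query
sizes.

The background universe defaults to the union of all genes annotated in
the queried databases, overridable by an explicit universe; both
conventions are common in over-representation analysis and the choice
materially affects p-values, so it is an explicit, logged parameter.
Query genes outside the background are dropped with a warning. When
several databases are queried together, q-values are computed jointly
across all tested pathways — one hypothesis family per run — not per
database.

Multiplicity is controlled with the Benjamini–Yekutieli step-up
($q_{(i)} = \min_{j \ge i} \min(1,\, p_{(j)}\, m\, c(m) / j)$,
$c(m) = \sum_{k \le m} 1/k$), which is valid under arbitrary dependency
— the appropriate regime for pathway collections, whose gene sets
overlap heavily. The implementation delegates to `stats::p.adjust`; the
test suite verifies it against an independent implementation of the
step-up definition to $10^{-12}$, and checks a null-query simulation
stays below the nominal 5% rate.

Three filters then annotate each result: fewer than 2 query genes in the
pathway (`too_few_query_genes`), pathway larger than 300 genes
(`pathway_too_large`), q-value above 5% (`not_significant`). The discard
rules are strict exceedances, so the boundaries 2, 300 and 0.05 pass.
All failing reasons are recorded independently and nothing is dropped
from the output — `passes_filters` marks the surviving rows.

## Pathway networks, modules and clustering

`build_network()` connects pathways whose overlap coefficient is at
least the threshold (default 0.2); edges strictly below it are removed,
equality is kept. Modules are defined as connected components with at
least two pathways — the minimal, parameter-free grouping rule
consistent with a thresholded similarity graph; isolated pathways are
reported as unassigned rather than forced into singleton modules.
Community-detection algorithms (Louvain and friends) are deliberately
not used: thresholding plus components is fully deterministic and has no
resolution parameter. Note that while the number of connected components
is monotone in the threshold, the number of *modules* need not be — a
two-pathway module dissolves into two unassigned nodes when its edge is
cut.

`cluster_dendrogram()` performs agglomerative average-linkage (UPGMA)
clustering on the distance $1 - S$. Average linkage is implemented
directly (naive $O(n^3)$ agglomeration) rather than through
`stats::hclust` for one reason: tie-breaking. Overlap coefficients are
coarse rationals, ties are routine, and `hclust`'s tie resolution is an
implementation detail. We instead merge, among all minimum-distance
cluster pairs, the pair whose sorted member keys are lexicographically
smallest — making every tree bit-reproducible. The result is a standard
`hclust` object (usable with `cophenetic()`, `cutree()`,
`ape::as.phylo()`), and the test suite verifies it against both
`stats::hclust` on tie-free fixtures and an independent
definition-based UPGMA oracle with the same tie-break rule.

`assign_to_closest_module()` attaches each unassigned pathway to the
module of its nearest assigned leaf by cophenetic distance on that
dendrogram, breaking ties toward the smallest module id. Pathways remain
unassigned only when no module exists at all.

`overlap_regions()` computes the disjoint region counts behind an Euler
view of up to 6 gene sets ($2^n - 1$ signatures; counts always sum to
the union size), and `module_core_genes()` intersects a module's member
sets to expose the shared core mediating its cross-talk.

## Mapping catalog

Two relation types are curated: `equivalentTo` (undirected — both
pathways describe the same process) and `isPartOf` (directed — side 1 is
a sub-process of side 2). Of the curation requirements, only the gene
criterion — at least one shared gene — is mechanically enforceable;
scope and biological context are human judgments and live outside the
data model. `isPartOf` deliberately does **not** require
$\text{genes}(child) \subseteq \text{genes}(parent)$: hierarchical scope
is a statement about biology, not strict set containment.
`equivalentTo` mappings are stored in canonical orientation
(lexicographically smaller `(resource, pathway_id)` first), making
lookups order-independent. Intra-database mappings are permitted;
pathways flagged as imported from another resource are suppressed from
suggestion output.

Suggestion scores every candidate on both metrics independently. The two
rankings must be combined into one order for presentation; the default
combiner is $\max(\text{content}, \text{lexical})$ — a candidate strong
on either axis surfaces — with content-only and lexical-only available.
This combiner is a package choice; the dual scores are always reported
so a curator can re-rank.

Voting: each curator holds exactly one vote ($\pm 1$; revoting
replaces), the proposer's proposal counts as $+1$, and a mapping is
accepted automatically when the net sum strictly exceeds 3. Acceptance
is a pure function of the vote multiset. The mirror-image rule — net sum
strictly below $-3$ — marks a mapping rejected; no rule for rejection
was otherwise fixed, so we chose symmetry.

`merge_consensus()` accepts mappings proposed identically in a majority
($\lfloor n/2 \rfloor + 1$) of curator catalogs, carries minority
mappings as proposed-and-flagged, and never auto-resolves
relation-type conflicts (same pair, different relation) — those are
excluded and reported.

`infer_hierarchy()` closes the accepted relations: symmetric closure of
`equivalentTo`, transitive closure of `isPartOf`, and substitution
through equivalence classes (if $A \equiv B$ and $B \sqsubseteq C$ then
$A \sqsubseteq C$). Closure is idempotent, and any cycle in the
`isPartOf` reachability (including cycles created via equivalences) is a
consistency error naming the members involved.

## Synthetic benchmarks

`generate_synthetic()` builds a universe of synthetic gene tokens
(`G000001`, ...), a reference database of uniformly-sized random gene
sets with names drawn from a 40-word biological vocabulary (three
distinct words per name, so lexical matching is meaningfully exercised),
and further databases containing noisy copies of a fraction of the
reference pathways — the planted `equivalentTo` truth. Noise is an
independent per-gene Bernoulli swap (drop + replacement from the
universe, preserving set size, so the expected overlap coefficient of a
planted pair is roughly $1 - \text{rate}$) and a fixed number of random
single-character name edits. Optional hierarchy levels add parents that
union pairs of the previous level plus extra genes, so child sets are
strict subsets of parents and the planted `isPartOf` pairs have
$S = 1$. All randomness flows from the single spec seed through an
isolated RNG stream; the global state is untouched and identical specs
produce byte-identical GMT output.

What the generator emulates: multi-database redundancy, partial overlap,
name drift, and hierarchical containment. What it does not: realistic
pathway topology, the long-tailed size distributions of real resources,
shared-core gene structure between unrelated pathways, or non-HGNC
identifier noise. Tests passing on these fixtures therefore validate the
*algorithms* (recovery, calibration, closure laws), not the curation
quality achievable on any particular database release — the published
mapping counts for real databases depend on specific releases and human
judgment and are not reproducible from code.

`score_recovery()` scores per truth-involved pathway: a hit when any
planted partner — taken from the symmetric-transitive closure of the
planted pairs, since two copies of the same reference pathway are
interchangeable partners — appears in the top $k$ suggestions. At zero
noise, top-1 recovery is exactly 1.

## Numerical and degenerate-input choices

- Empty gene sets are representable; constructors and readers warn
  (classed conditions) instead of failing, and empty sets score 0
  similarity.
- Ties: agglomeration ties break lexicographically (above); suggestion
  and closest-module ties break by `(resource, pathway_id)` / smallest
  module id; every output table is sorted on a documented key, so all
  outputs are bit-reproducible and CLI reruns are byte-identical
  (outputs carry no timestamps).
- Histogram bins for pathway sizes: unit-width integer bins to 50, then
  geometric bins with edge ratio 1.5 — deterministic, plot-ready.
- p-values are validated to $[0, 1]$; overlap counts to
  $[0, \min(K, n)]$.
- Problem sizes used by the test and acceptance runs — complete
  enumeration of enrichment tables to universe 60, 1000-replicate null
  calibration on a 40-pathway database, 50 eight-pathway clustering
  fixtures, and five-seed recovery grids on 3×100-pathway universes —
  were chosen to exercise every code path at full coverage while keeping
  a complete run in the low minutes on one core.

## Known limitations

- Single gene namespace; no identifier cross-mapping or species
  handling.
- No topology-, rank- (GSEA) or ontology-based methods: gene sets only.
- The similarity matrix is dense; collections beyond a few thousand
  pathways per comparison will want blocking, which is out of scope.
- The voting model is a flat net sum; no curator weighting or
  authentication semantics are modelled.
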