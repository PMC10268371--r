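---
title: "Comparing pseudoknotted RNA secondary structures and evaluating the comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing pseudoknotted RNA secondary structures and evaluating the comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pktaxa)
```

## The problem

Ribosomal RNAs (5S, 16S, 23S) fold into secondary structures that are far
better conserved than their sequences, which makes structure comparison a
natural instrument for grouping organisms into taxa. The difficulty is
that many of these structures contain *pseudoknots* — base pairs that
cross in the arc-diagram representation — and the classical
structure-as-tree encodings underlying most comparison tools break down
exactly there.

`pktaxa` implements a complete evaluation pipeline for comparison methods
that tolerate crossings: four dissimilarity methods, agglomerative
clustering over any pairwise dissimilarity matrix, and label-based
clustering metrics. Given a set of molecules with reference labels (for
instance phyla from a curated taxonomy), a method is judged by how well
clustering its dissimilarities recovers the labels.

## The arc-diagram model

A structure is `rna_structure(length, pairs)`: positions `1..n` on a
backbone and a set of arcs `(i, j)`, `i < j`. Three invariants are
enforced at construction: one partner per position, arcs joining
non-consecutive positions (`j ≥ i + 2`), and indices within bounds. Two
arcs `(i, j)` and `(k, l)` with `i < k` cross iff `i < k < j < l`; a
structure is pseudoknot-free iff `crossing_pairs()` is empty.

Formats: BPSEQ and CT (position/partner tables) and dot-bracket-letter
(per-family stack matching, with `()[]{}<>` and letter families) are read
and written in both headered and header-free dialects. The dot-bracket
writer assigns families greedily, first-fit into the family order
`() [] {} <> A..Z`, so nested structures use only `()` and each extra
"layer" of crossing opens a new family. Multi-strand complexes are out of
scope; they can be handled upstream by concatenating the strands into one
backbone.

## The four dissimilarities

**Genus.** The genus `g` of the diagram is the number of handles a sphere
needs for the diagram to embed without crossings. We compute it by the
fatgraph boundary walk in its chord-diagram form: collapse the backbone to
a single fatgraph vertex whose cyclic order lists the `2n` arc endpoints;
with `τ` the endpoint involution along arcs and `σ` the cyclic order, the
boundary loops are the cycles of `σ∘τ`, and `2g = n − r + 1`. The
structure's `boundary_cycles` are returned so the conservation property
(every endpoint slot lies in exactly one cycle) is auditable. Stacked
helices provably do not change `g` (the tests assert this), and `g` is
additive over concatenation on disjoint intervals. The dissimilarity is
`|g₁ − g₂|`.

**Pseudoknot order.** A *region* is a maximal stack of consecutively
nested pairs with no unpaired nucleotide inside the run. Regions are the
vertices of a conflict graph whose edges are crossings. The order is
computed by layering: layer 0 is a maximum-cardinality crossing-free
subset of regions, layer 1 a maximum crossing-free subset of the rest,
and so on; the structure's order is the deepest layer index. The
literature also phrases the order as "the minimum number of regions to
remove to become pseudoknot-free"; the two readings diverge on some
conflict graphs (odd cycles, for instance), and this package deliberately
implements the layering reading, which matches the iterative
order-assignment description and the dot-bracket-letter encoding usage.
Two further choices matter and are documented here because the layer
count itself can depend on them:

* *Exact mode* (default) finds each maximum independent set by exhaustive
  branch-and-bound, with ties broken towards the lexicographically
  smallest set of region indices (regions ordered by opening position).
  It refuses more than `max_exact_regions = 20` regions.
* *Greedy mode* repeatedly takes the minimum-degree region (ties: smallest
  index). It always produces a valid crossing-free layering but can
  produce more layers than exact mode on dense conflict graphs; the two
  agree on the structure families produced by the package generators.

**ASPRA.** Each structure with ≥ 1 arc becomes a binary operator tree:
repeatedly select the arc with the rightmost endpoint and classify its
relation to the remaining arcs — crossing (annotated with the number of
arcs crossed) if it crosses any, else nesting if its interval encloses
the remainder's span, else concatenation; the left child is the tree of
the remainder, the right child the selected arc's leaf. Crossing is given
precedence in mixed situations because it is the most informative
relation. The ASPRA distance is the minimum-cost ordered tree alignment
of the two trees, computed with the classical ordered-forest alignment
recurrences (tree-tree, forest-forest over child spans, plus the two
cases that align a node against an inserted counterpart whose children
absorb a sub-forest). Costs come from a configurable scheme; the default
is unit costs with replacement 0 iff labels are equal, where a crossing
node's label includes its crossing count (the count is treated as part of
the label because the original cost constants are not published). The
test suite checks the dynamic program against an independent exhaustive
recursion that enumerates all alignments of small trees.

**RAG-2D.** The dual graph has one vertex per stem and one edge per
single strand of more than one unpaired nucleotide connecting structural
elements; hairpin loops of > 1 nt give self-loops, and the 5'/3' dangling
ends give nothing. A stem is a maximal helix; helices separated by
bulges/internal loops of ≤ 1 unpaired nt per strand merge into one vertex
(configurable via `merge_gap`), consistent with the > 1 nt edge
threshold; single-pair stems are admitted. The Laplacian is `L = D − A`
with edge multiplicities in `A`, `a_ii = 2` per self-loop, and degrees
counting edge endpoints — the only convention under which `L` keeps zero
row sums and `λ₁ = 0`, both of which the representation requires. The
features are obtained from the unit-norm eigenvector of the Fiedler value
`λ₂`: sort ascending to `v`, scale by `ṽᵢ = vᵢ(n − 1)/(vₙ − v₁)`, then
least-squares regress `ṽᵢ` on `i` to get slope `s` and mean squared
residual `e`. The scaling denominator deserves a note: the formula is
sometimes typeset with `vₙ − vᵢ`, which is singular at `i = n`; the
`vₙ − v₁` reading is the only one defined for all components and
coincides with the printed form at `i = 1`, so that is what is
implemented. Signs are fixed by choosing the orientation whose sorted
vector is lexicographically smallest; for degenerate `λ₂` the
eigen-solver's deterministic basis is used, and the permutation-invariance
guarantees are stated (and tested) for simple Fiedler values only. Graphs
with fewer than two vertices yield the sentinel `(0, 0)`; disconnected
dual graphs (λ₂ = 0) are an error. Molecules are compared by the
Euclidean distance on `(s, e)`.

## Clustering and metrics

Agglomerative clustering starts from singletons and repeatedly merges the
closest clusters, updating inter-cluster dissimilarity by the linkage
rule (single = min, complete = max, average = mean over member pairs);
the dendrogram is cut at `k` clusters, and `k` is always the number of
distinct reference labels. Ward linkage is excluded on purpose: it
presumes Euclidean distances, which these methods do not produce. The
merging itself is delegated to `stats::hclust` (it is not this package's
contribution); its tie handling is deterministic, and the suite checks
determinism, monotone merge heights, the single-linkage = MST-cut
identity (against an independent graph library) and exact recovery of
planted blocks. Matrices must be symmetric (asymmetries ≤ 1e−9 are
averaged away, anything larger is an error), non-negative and finite.
Similarity matrices are converted by min–max normalisation to [0, 1]
followed by `diss = 1 − sim`, diagonal forced to 0; a constant matrix
converts to all zeros with a warning.

The metrics are the rand index (pair-counting: `R = (a + b)/(a + b + c +
d)`, denominator `n(n−1)/2`), homogeneity `h = 1 − H(C|K)/H(C)` and
completeness `c = 1 − H(K|C)/H(K)` with Shannon entropies over the
class/cluster contingency counts. Conventions: `0·log 0 = 0`, and a zero
reference entropy (`H(C) = 0` or `H(K) = 0`) yields a score of 1 — this
is what makes a set whose molecules all share one label score perfectly
under every method and linkage, a degenerate case the pipeline must (and
does) reproduce. The scores are independent of the logarithm base;
natural logs are used internally. Completeness equals homogeneity with
the two labelings swapped, which the suite verifies on thousands of
fuzzed cases rather than by sharing code between the two functions.

## What the generators emulate — and what they do not

`gen_nested_structure()` assembles 3–6 helices of 3–6 stacked pairs by
random nesting/concatenation with loops of 3–6 nt: the scale and shape of
a small rRNA-like fold, pseudoknot-free by construction.
`gen_pseudoknotted_structure()` inserts helix pairs in the interleaved
pattern `A..B..A'..B'` at disjoint windows — the construction gives exact
control of the region conflict graph, so the target crossing-pair count
(and hence order and genus) is planted, not estimated. The `"clique"`
pattern produces `k` mutually crossing regions for order `k − 1`.
`gen_planted_partition()` draws within-taxon dissimilarities around mean
0.2 (sd 0.05) and between-taxon around 1.0 (sd 0.1) — a separated regime
standing in for molecule sets whose taxa are genuinely distinguishable;
negative draws are clamped at zero and counted. All generators are pure
functions of `(seed, call-site tag)`, so adding a generator never shifts
an existing fixture stream.

These synthetic inputs validate the machinery, not the biology: passing
tests show the methods compute what they claim and that the pipeline
recovers partitions that are recoverable. Real rRNA benchmarks have
unbalanced taxa, correlated structural variation within taxa, and
dissimilarity distributions far from block-normal, so scores on real data
are expected to be (much) lower and method-dependent, exactly the
comparison the framework exists to make.

## Numerical choices and problem sizes

* Pair storage is 1-based with `i < j`, matching BPSEQ/CT conventions.
* Exact-order cap 20 regions; the oracle suites work at ≤ 10 regions.
* Alignment DP memoises tree-pair and forest-span tables; pairwise ASPRA
  matrices are intended for benchmark-scale sets (hundreds of molecules,
  tens of arcs each), not genome-scale inputs.
* The clustering implementation is O(n³) at worst via `hclust`; the
  intended scale is n ≤ ~500 molecules.
* The test suite sizes were chosen to exercise every property at desk
  scale: 1000 seeded structures for the genus/crossing equivalence, 100+
  seeded tree pairs against the exhaustive alignment oracle, 10⁴ fuzzed
  label pairs for metric bounds and duality, planted 3-block recovery at
  n = 60.

## Known limitations

* Multi-model CT files, tertiary-structure formats and base-pair type
  annotation are not parsed.
* The pseudoknot-order layering is one of several inequivalent readings
  of the order; comparisons against tools implementing a removal-count or
  MILP formulation may differ on adversarial conflict graphs.
* ASPRA costs default to unit values; distances are comparable within one
  scoring scheme only, and no attempt is made to reproduce the numeric
  output of any specific alignment tool.
* RAG-2D features are only defined for connected dual graphs with ≥ 2
  stems; molecules reduced to a single stem all collapse to the sentinel
  `(0, 0)`.
* Automatic selection of the cluster count is out of scope: `k` always
  comes from the reference labels, as the evaluation design dictates.
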