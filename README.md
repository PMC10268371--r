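# pktaxa

Comparison of RNA secondary structures **with pseudoknots**, and evaluation
of how well a comparison method recovers a known grouping of molecules —
for example the taxa of 16S/23S/5S rRNAs at a chosen taxonomy rank.

Most RNA comparison tools map a secondary structure to a tree and stop
working as soon as base pairs cross (a pseudoknot). `pktaxa` implements an
evaluation pipeline for methods that do handle crossings:

1. **Read** structures in BPSEQ, CT or dot-bracket-letter format (headered
   or header-free dialects).
2. **Compare** all pairs of molecules with one of four dissimilarities:
   * **genus** — the topological genus *g* of the arc diagram, computed by
     the fatgraph boundary walk (*2g = n − r + 1* with *n* arcs and *r*
     boundary loops); dissimilarity `|g₁ − g₂|`;
   * **pskorder** — the pseudoknot order: regions (maximal helix stacks)
     are layered into crossing-free sets, the deepest layer index is the
     order; dissimilarity `|o₁ − o₂|`;
   * **aspra** — the ASPRA distance: each structure becomes a binary
     operator tree over concatenation (⊙), nesting (⋒) and crossing (⋈,
     annotated with the crossing count), and the minimum-cost ordered tree
     alignment `d(S₁, S₂) = min { σ(L) : L an alignment of t₁, t₂ }` is
     computed by dynamic programming;
   * **rag2d** — dual-graph spectral features: stems are vertices, single
     strands of > 1 unpaired nucleotide are edges; the sorted, scaled
     Fiedler vector of the graph Laplacian `L = D − A` is regressed on its
     rank, and molecules are compared by the Euclidean distance between
     their `(slope s, MSE e)` pairs.
3. **Cluster** the dissimilarity matrix by agglomerative clustering
   (single, complete or average linkage), cutting the dendrogram at as
   many clusters as there are distinct reference labels.
4. **Score** the partition against the reference labels with the rand
   index `R = (a + b)/(a + b + c + d)`, homogeneity
   `h = 1 − H(C|K)/H(C)` and completeness `c = 1 − H(K|C)/H(K)`, all
   in [0, 1] with 1 meaning perfect recovery.

Seeded generators for nested and pseudoknotted structures and for
planted-partition distance matrices make every stage testable without any
external download. External distance matrices (e.g. from other alignment
tools) plug in unchanged through the distance-CSV interface.

## Worked example

```r
library(pktaxa)

x <- parse_dotbracket("((..[[[..))..]]]")
x
#> RNA secondary structure: 16 nt, 5 base pairs, 6 crossing arc pairs (pseudoknotted)
genus(x)
#> genus 1 (n = 5 arcs, r = 4 boundary loops)
pseudoknot_order(x)
#> pseudoknot order 1 (2 regions)
```

The two helices cross, so the diagram needs one handle (genus 1) and one
of the two regions must be lifted to layer 1 (order 1).

A full evaluation run on a synthetic labelled set — three taxa whose
members differ in pseudoknot complexity:

```r
set <- gen_labeled_structures(generator_config(seed = 42, n_molecules = 12, n_taxa = 3))
D <- compute_distance_matrix(set$structures, method = "genus")
taxa_cluster(D, set$labels)
#> Agglomerative clustering of 12 molecules into 3 clusters
#>   linkage rand_index homogeneity completeness
#>    single          1           1            1
#>  complete          1           1            1
#>   average          1           1            1
```

The genus separates these taxa exactly (they were planted with 0, 1 and 2
crossing region pairs), so every linkage recovers the taxonomy perfectly.
A finer method sees finer differences and no longer groups molecules into
exact invariant classes:

```r
Da <- compute_distance_matrix(set$structures, method = "aspra")
taxa_cluster(Da, set$labels)
#> Agglomerative clustering of 12 molecules into 3 clusters
#>   linkage rand_index homogeneity completeness
#>    single      0.742       0.555        0.593
#>  complete      0.742       0.555        0.593
#>   average      0.682       0.493        0.564
```

## Command line

A thin CLI over the same functions is installed with the package
(`system.file("scripts", "pktaxa", package = "pktaxa")`):

```sh
pktaxa fixtures  --seed 5 --n 12 --taxa 3 --out fx
pktaxa distances --method rag2d --in fx/bpseq --out matrix.csv
pktaxa cluster   --labels fx/labels.csv --distances matrix.csv --rank taxon --out report.csv
```

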