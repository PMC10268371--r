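Package: pktaxa
Title: Evaluation Framework for Comparison Methods of Pseudoknotted RNA
    Secondary Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing RNA secondary structures that contain
    pseudoknots and for evaluating how well a comparison method recovers a
    known grouping (for example a curated taxonomy) of a set of molecules.
    Reads and writes BPSEQ, CT and dot-bracket-letter files; computes four
    structure dissimilarities (the genus topological invariant, the
    pseudoknot order, the ASPRA tree-alignment distance and RAG-2D dual-graph
    Fiedler-vector features); runs agglomerative clustering with single,
    complete or average linkage on any pairwise dissimilarity matrix; and
    scores the resulting partition against reference labels with the rand
    index, homogeneity and completeness. Seeded generators for nested and
    pseudoknotted structures and planted-partition distance matrices make
    the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    igraph,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
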