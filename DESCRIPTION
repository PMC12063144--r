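Package: persistATAC
Title: Single-Cell Chromatin Accessibility Analysis of Drug-Tolerant
    Persister Subpopulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for single-cell ATAC-seq analysis
    of drug-tolerant persister (DTP) subpopulations in targeted-therapy
    models: per-cell quality control (fragment count, TSS enrichment,
    synthetic-doublet kNN enrichment), tile/gene/peak/motif feature
    matrices, iterative LSI embedding and modularity clustering, marker
    signatures at FDR and fold-change thresholds, projection of signatures
    onto a directed regulatory network with hypergeometric key-driver
    calling, per-cell repressive-chromatin scoring from ChIP-seq broad
    domains with graph-diffusion smoothing, cluster-path pseudotime and
    trajectory-differential motif statistics. Ships a synthetic fragment
    simulator with planted ground truth so every stage is testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    irlba,
    RANN,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
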