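Package: xenoGerm
Title: Dual-Species Single-Cell Analysis of Transplanted Germ Cells
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing single-cell RNA-seq experiments in which
    rat spermatogonial stem cells are transplanted into mouse testes and
    recovered cells must be demultiplexed by species before germ-cell
    analysis. Provides a seeded dual-genome UMI count simulator with a
    seven-stage spermatogenic lineage model and planted treatment effects;
    per-cell species assignment by a dual-genome UMI-margin rule; QC
    filtering, CPM log-normalisation, marker-panel cell typing and a
    linear pseudotime; pseudobulk aggregation with PCA and a permutation
    PERMANOVA; threshold-based differential expression with
    Benjamini-Hochberg correction and Euler-style set overlaps; gene
    program module scores with binned control genes, apoptotic-cell
    classification, and per-replicate cell-type proportion ANOVA. A
    run-all pipeline ties the stages together behind a single
    configuration object with MatrixMarket/TSV/JSON input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
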