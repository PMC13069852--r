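Package: aucmarker
Title: Cell-Type Specificity of Genes via One-vs-Rest ROC AUC in Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how specifically each gene marks a cell type in
    labeled single-cell count data. Computes one-vs-rest ROC curves and
    AUCs for every gene and cell type at a chosen annotation level,
    classifies genes along the marker / preferentially-expressed /
    ubiquitous gradient (candidate markers at AUC >= 0.8, ubiquitous at
    AUC_max < 0.6), and compares AUC_max distributions between gene sets
    with two-sided Mann-Whitney U tests, a random-gene resampling null,
    and loss-of-function constraint (LOEUF) summaries. Includes a
    negative-binomial simulator that plants marker, differentially
    expressed and ubiquitous genes so the whole pipeline is testable
    without external atlases, readers and writers for sparse MatrixMarket
    and dense count tables, cell annotations, GMT gene sets and
    constraint tables, and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
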