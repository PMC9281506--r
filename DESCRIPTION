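Package: clonetraj
Title: Expression-Inferred CNV Subclones, Signature Cell Typing and
    Trajectory Scoring for Single-Cell Tumor Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for dissecting intratumoral heterogeneity
    in single-cell RNA-seq of ependymoma-like tumors: quality control and
    normalization of 10x-style UMI count matrices, expression-inferred
    copy-number profiles with 0-2 rescaling and quadratic-sum CNV levels,
    Ward-linkage subclone calling, gene-module signature scoring with
    binned control genes and SE/rSE cell-type classification, a
    stemness/differentiation trajectory score with sample-level survival
    stratification, Fisher-Pitman permutation tests of cell-type
    composition, and permutation-based ligand-receptor crosstalk scoring.
    Includes a negative-binomial synthetic-cohort generator with planted
    cell states, CNV subclones and survival outcomes so every stage is
    testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    cluster,
    mclust,
    survival
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
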