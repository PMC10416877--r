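Package: mtqsar
Title: Multi-Tasking QSAR Models for G-Quadruplex Ligand Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds multi-tasking (multi-condition) classification QSAR models
    for G-quadruplex ligand discovery. Covers chemical and biological data
    curation with two-stage duplicate analysis, a self-contained molecular
    descriptor backend, Box-Jenkins moving-average condition-modified
    descriptors, genetic-algorithm feature selection with Wilks-lambda and
    MCC fitness, linear discriminant and random forest classifiers with a
    full validation-metric suite, a three-method applicability domain
    (Tanimoto similarity, Euclidean distance, leverage) combined by a union
    rule, and a virtual-screening engine that evaluates compound libraries
    over enumerated experimental-condition grids for four G4-oriented
    endpoints (selectivity, interaction, stabilization, cytotoxicity).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    MASS,
    randomForest,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
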