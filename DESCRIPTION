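Package: scident
Title: Supervised Cell-Type Identification from Binarized Single-Cell
    Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns cell types to single-cell RNA-seq profiles with a small
    fully connected neural network trained on binarized (present/absent) UMI
    counts over a fixed reference gene space. Supports an expandable cell-type
    catalog with a mandatory "Unknown" class, synthetic "unknown" profiles
    built by within-cell gene shuffling, class-weighted training, continual
    learning by online updates with review (replay) training, transfer-learning
    catalog expansion with a frozen first hidden layer, information-gain
    ranking of per-type signature genes, and evaluation via concordance,
    confusion matrices, label-transition tables and stratified k-fold
    cross-validation. Reads and writes CellRanger-style Matrix Market triplets
    and dense delimited gene-by-cell tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
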