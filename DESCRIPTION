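Package: cypscreen
Title: Structure- and Ligand-Based Classification of CYP2C9 Inhibitors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for classifying small molecules as
    inhibitors or non-inhibitors of cytochrome P450 2C9 and for prioritizing
    virtual-screening hits. Curates activity tables into labeled, drug-like,
    diverse compound sets; computes open 2D/3D physicochemical descriptors;
    manages ensemble-docking interaction-energy profiles over seven receptor
    conformations; selects descriptors by repeated-forest mean Gini
    importance; trains random-forest and RBF support-vector classifiers under
    repeated stratified cross-validation; evaluates with confusion-matrix
    metrics and paired McNemar comparison; and applies a consensus-plus-energy
    screening cascade with two-stage Tanimoto diversity clustering. Seeded
    synthetic fixtures make every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    ranger,
    kernlab,
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
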