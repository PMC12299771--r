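Package: polygru
Title: Polymer Classification with a Bidirectional GRU and Metaheuristic
    Feature Selection and Tuning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for multi-class polymer classification
    from molecular structure. Converts SMILES strings to hashed circular
    (Morgan-type) binary fingerprints, standardizes features with median
    imputation, percentile capping and Z-scoring, selects informative
    features with a Bald Eagle Search wrapper driven by cross-validated
    nearest-neighbour error, classifies with a from-equations
    bidirectional gated recurrent unit network, and tunes its
    hyperparameters with a Zebra Optimization Algorithm. Includes a
    synthetic fingerprint/descriptor generator, a stratified evaluation
    battery (per-class and macro accuracy, precision, recall, F1, AUC),
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
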