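Package: fnirsCCA
Title: Proficiency Classification from fNIRS Activation Patterns via Sparse CCA
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A block-design analysis pipeline for functional near-infrared
    spectroscopy (fNIRS) studies of second-language proficiency. Provides a
    synthetic cohort simulator with a configurable hemodynamic response and
    physiological noise model, modified Lambert-Beer conversion, zero-phase
    band-pass filtering, epoching into fixed-length language blocks with
    linear baseline correction, a Welch-style per-channel activation
    indicator, L1-penalised sparse canonical correlation analysis with
    leave-one-out stability counting for informative-channel selection, and
    cross-participant classification (linear SVM, sparse logistic regression
    with automatic relevance determination, K-nearest neighbours) evaluated
    under leave-one-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    e1071,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    class,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
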