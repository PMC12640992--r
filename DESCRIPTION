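Package: panfuse
Title: Consensus Subtype Discovery, Cross-Attention Classification and
    Survival Risk Modelling for Bulk Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A voting ensemble of five clustering algorithms (k-means,
    Gaussian mixture, Ward agglomerative, CLARANS and PAM) produces
    consensus pseudo-labels for molecular subtypes of bulk expression
    data; a parallel CNN + bidirectional-LSTM classifier fused by scaled
    dot-product cross-attention is trained against those pseudo-labels;
    hub genes are selected by intersecting L1-regularised regression with
    random-forest permutation importance; and a prognostic risk model
    combines a univariate Cox screen, a random survival forest with
    log-rank splitting, a proportional-hazards risk function and
    stratification at a maximally selected rank-statistic cutoff. A
    synthetic-data generator with planted subtypes and linked survival
    outcomes makes every stage testable without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    cluster,
    survival,
    glmnet,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
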