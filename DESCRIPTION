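Package: mklconn
Title: Multi-Kernel SVM Classification of Multi-Weight Structural Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds fiber-number, fractional-anisotropy and mean-diffusivity
    weighted brain networks that share one topology, vectorizes them into
    edge-feature tables, ranks features by the two-class F-score or lasso,
    and classifies subjects with a multiple-kernel support vector machine
    whose per-network kernel weights are learned on the probability simplex.
    Evaluation uses leakage-safe leave-one-out cross-validation with
    fold-wise normalization and feature selection, grid search over the box
    constraint and feature fraction, confusion metrics and rank-statistic
    ROC/AUC. Consensus features selected in every fold are weighted by
    absolute hyperplane coefficient times the network kernel weight and
    aggregated per edge and per network. A synthetic cohort generator with
    controllable group effects makes the full pipeline testable without
    MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    kernlab,
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
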