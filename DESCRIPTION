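Package: flowconn
Title: Information Flow Rate Connectivity and Recurrent-Network
    Classification for Resting-State EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for directed (effective) connectivity analysis of
    source-reconstructed EEG and for raw-EEG classification. Implements
    the normalized Liang-Kleeman information flow rate between region
    of interest (ROI) time series, permutation-based significance
    thresholds, group-level pooled-distribution comparison
    (Kolmogorov-Smirnov, Kruskal-Wallis, Cohen's d, subsampled shape
    features), and weighted directed degree assortativity of the
    resulting networks. A second track provides a bidirectional LSTM
    classifier for fixed-length multichannel EEG epochs with strictly
    subject-wise ensemble cross-validation, confusion-matrix metrics
    and ROC/AUC summaries. A seeded synthetic-cohort generator with
    known ground-truth couplings makes every stage testable without
    access to restricted clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
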