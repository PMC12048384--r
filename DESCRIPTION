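Package: cbbgwo
Title: Cluster-Guided Binary Grey Wolf Optimization for Tripeptide-Based
    Protein Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Wrapper feature selection for multiclass protein-sequence
    classification. Sequences are encoded as 8000-dimensional tripeptide
    composition (TPC) frequency vectors; pairwise mutual information
    between features drives a k-means partition of the feature space, and
    a binary grey wolf optimizer is run inside each cluster so that a
    compact, non-redundant feature subset can be assembled from the
    per-cluster winners. Includes One-vs-Rest multiclass evaluation with
    five classifiers, ROC/AUC utilities, and a planted-motif synthetic
    sequence generator that provides ground truth for feature-recovery
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    e1071,
    kernlab,
    glmnet,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
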