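Package: batchlens
Title: Root-Cause Diagnosis of Productivity Differences in Fed-Batch Cell
    Culture from Inline and Offline Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A four-stage pipeline for diagnosing productivity differences
    between fed-batch cell-culture batches from inline sensor time series and
    offline assay tables. Stages: data preprocessing (missing-data imputation,
    spike repair, low-information variable filtering), phase division by a
    moving-window k-nearest-neighbour set distance, functional-data-analysis
    feature extraction (B-spline and polynomial basis coefficients per stable
    phase) fused with batch-wise unfolded offline data, and contrastive-cluster
    principal component analysis (ccPCA) to rank the features that distinguish
    high- from low-productivity batches. Includes a synthetic fed-batch
    bioreactor data generator with known phase structure, injectable data
    defects, and cluster-level effects so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    splines,
    Rcpp,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
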