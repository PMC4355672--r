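Package: wrda
Title: Weighted Relative Difference Accumulation for Two-Group Time-Series
    Metabolomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks discriminative features in short two-group (control versus
    model) time-series metabolomics experiments by weighted relative
    difference accumulation (wRDA) and its sampling-time-weighted extension
    (w2RDA). Provides LC-MS feature-table preprocessing (zero-fraction
    filtering, sigma-range outlier correction), stratified label-permutation
    null distributions with SAM-style false discovery rate estimation, grid
    optimization of time-point and sampling-time weight functions, a
    two-level noise-filter-then-rescore workflow, repeated cross-validated
    SVM and ROC/AUC validation, and a synthetic data generator with planted
    group-divergence trajectories. Datasets are represented as
    SummarizedExperiment objects carrying group, time-point and
    sampling-time metadata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    e1071
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Metabolomics, TimeCourse, FeatureExtraction, Classification
RoxygenNote: 7.3.3
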