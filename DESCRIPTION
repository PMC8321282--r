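Package: ecgscreen
Title: Binary Anomaly Screening of Single-Lead ECG Segments with a 1D
    Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Screens 15-second single-lead electrocardiogram segments for
    any kind of cardiac anomaly with a four-block 1D convolutional neural
    network implemented from scratch in R. Provides readers and writers for
    MIT-BIH-style tabular signal and beat-annotation exports, fixed-window
    segmentation with annotation-driven binary labeling, class balancing by
    undersampling, segment-wise and patient-wise (record-disjoint) evaluation
    splits with stratified k-fold plans, confusion-matrix metrics, a
    patient-level alerting rule, and a seeded synthetic annotated-ECG
    generator so the full pipeline is testable without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
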