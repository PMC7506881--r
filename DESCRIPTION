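Package: mddnet
Title: Multilevel Wavelet Densely Connected Network for Single-Lead ECG
    Cardiovascular Disease Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A complete pipeline for four-class cardiovascular disease
    classification (Normal, myocardial infarction, coronary artery disease,
    congestive heart failure) from raw single-lead ECG at heterogeneous
    sampling rates.  Provides adaptive sample-frequency segmentation without
    R-peak detection, two-dimensional multilevel Haar wavelet decomposition
    of segment images, a densely connected convolutional network fused with
    a multilevel wavelet feature branch (implemented natively with 'Rcpp'
    kernels), Borderline-SMOTE oversampling and a focal loss for class
    imbalance, intra-patient and subject-disjoint inter-patient evaluation,
    additive white Gaussian noise robustness experiments, and a synthetic
    multi-subject ECG generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
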