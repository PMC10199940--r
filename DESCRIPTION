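Package: eegmarkers
Title: Complexity, Network and Wavelet Markers for EEG Group Discrimination
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for screening electroencephalography (EEG) biomarkers that
    separate patients with Alzheimer's disease from healthy elderly controls.
    Implements six time-series measures (Morlet wavelet coherence, the Katz
    fractal dimension, quadratic entropy, relative wavelet energy, the
    quantile-graph mean jump length and a visibility-graph complexity index),
    dyadic Daubechies-4 band decomposition of EEG channels, ANOVA and ROC-AUC
    group-discrimination screening with parameter scans, support-vector-machine
    classification of individual subjects under stratified cross-validation, a
    computational-cost benchmark across series lengths, and a synthetic EEG
    cohort generator for calibration and null studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
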