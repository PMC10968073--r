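Package: hasdetect
Title: Deep Convolutional Detection of High-Amplitude Stereotypic
    Seizures in Post-Hypoxia-Ischemia EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A reproducible pipeline for detecting high-amplitude
    stereotypic evolving seizures (HAS) in continuous 256 Hz
    electroencephalography recorded after hypoxia-ischemia. Provides a
    synthetic fetal-sheep-like EEG cohort generator with ground-truth
    annotations, per-minute EEG power trends and a robust
    moving-median-absolute-deviation seizure-centering algorithm, three
    convolutional front-ends (Morlet wavelet scalogram images, a
    three-column wavelet/Fourier dominant-feature matrix, and raw
    segments), compact convolutional network classifiers trained with
    RMSProp, and an evaluation harness covering leave-one-group-out and
    stratified k-fold cross-validation with confusion-matrix metrics and
    ROC/AUC summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
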