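Package: anxeeg
Title: EEG-Based Anxiety State Detection with Wavelet and Spectral Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for detecting anxious states from
    multi-channel EEG. Generates synthetic Emotiv EPOC-style recordings with
    controllable class structure, band-pass filters and epochs recordings,
    labels epochs from Self-Assessment Manikin (SAM) valence/arousal ratings
    or Hamilton Anxiety Rating Scale (HAM-A) scores, extracts Daubechies-4
    wavelet and power-spectral-density features together with eight frontal
    valence/arousal asymmetry features, balances classes with SMOTE, and
    benchmarks six classifiers (k-NN, LDA, RBF-SVM, random forest, AdaBoost,
    gradient boosting) with accuracy, precision, recall, ROC/AUC and Cohen's
    kappa.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    MASS,
    class,
    e1071,
    randomForest,
    rpart,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
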