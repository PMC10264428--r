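Package: remhf
Title: Discriminating REM Sleep from Wakefulness in Mice Using
    High-Frequency EEG Band Power
Version: 0.1.0
Authors@R:
    person("remhf", "developers", email = "remhf@example.org", role = c("aut", "cre"))
Description: An EEG-only pipeline for separating rapid-eye-movement sleep
    (REMS) from wakefulness in rodent polysomnography. Provides a seeded
    synthetic EEG/EMG generator with circadian state structure, semi-automated
    threshold scoring of 4-s epochs, artifact excision and nine-band spectral
    feature extraction (0.1-500 Hz) with iterative Grubbs outlier replacement,
    a from-scratch kernel-density naive Bayes classifier with QDA and k-NN
    comparators, and an evaluation protocol based on repeated shuffled
    train/test splits, ROC/AUC, single-band false-negative-ratio ablation and
    nonparametric tests. Signals are exchanged as EDF, hypnograms and feature
    tables as CSV, models and reports as JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
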