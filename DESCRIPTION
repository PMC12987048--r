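Package: eegscreen
Title: Three-Channel Resting-State EEG Depression Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for screening major depressive disorder from
    three frontal EEG channels (Fp1, Fz, Fp2) recorded eyes-closed at rest.
    Reads EDF and three-column CSV recordings, applies per-recording z-scoring,
    overlapped fixed-length windowing and quality control, computes Welch
    relative band powers, differential entropy and spectral-ratio features,
    trains a hybrid Conv1D/feature-fusion classifier (with plain Conv1D and
    squeeze-and-excitation baselines) under subject-independent splits with
    label-preserving augmentation and MixUp, and aggregates window predictions
    to subject level by majority voting with Wilson confidence intervals,
    Matthews correlation, Cliff's delta and bootstrap effect summaries. A
    synthetic eyes-closed frontal-EEG cohort generator makes the whole pipeline
    testable without any recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    glmnet,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
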