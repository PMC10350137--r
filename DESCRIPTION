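Package: somnokit
Title: Sleep Staging and Sleep Parameter Estimation from Wrist-Worn
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for measuring sleep from raw wrist-worn tri-axial
    accelerometry. Implements the full measurement pipeline: preprocessing
    and non-wear quality control of raw traces into 30-second epochs; a
    deep sequence classifier (1D residual convolutional encoder, a
    bi-directional LSTM across the night, and two fully-connected layers)
    that assigns AASM five-stage sleep labels to each epoch, with optional
    multi-task self-supervised pretraining of the encoder; a random-forest
    baseline on hand-crafted spatiotemporal features with hidden-Markov
    smoothing; free-living sleep-window detection (window merging and
    longest-window-per-noon-to-noon selection); derivation of per-night
    sleep parameters (total sleep duration, efficiency, WASO, REM/NREM
    durations and ratios) and weekly summaries under wear-time criteria;
    and validation statistics (Cohen's kappa, macro-F1, balanced accuracy,
    Bland-Altman limits of agreement, subject-wise cross-validation,
    intraclass correlation, and a wear-time missingness simulation). A
    synthetic-data module generates accelerometry with known hypnograms so
    the whole pipeline is testable without any cohort download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
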