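Package: vitalattn
Title: Hybrid Attentive CNN-BiLSTM Classification of Multichannel Vital Signs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts an impending medical intervention from a short window of
    multichannel physiological monitoring data (high-frequency waveforms such
    as ECG alongside 1 Hz vital signs) using a hybrid convolutional and
    bidirectional LSTM network with two knowledge-driven attention mechanisms:
    a segment-level "fluctuant" attention scored from per-segment standard
    deviations, and a channel-level "trend" attention scored from the range of
    min-max-scaled segment means. Includes record ingestion and cubic-spline
    imputation, event-aligned window extraction and segmentation, a seeded
    synthetic vital-sign generator with ground-truth anomaly locations,
    training and evaluation pipelines with ablation variants, and export of
    attention weights for interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    pROC,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
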