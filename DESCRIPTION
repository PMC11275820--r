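Package: grangercl
Title: Granger-Causality Spatial-Temporal Contrastive Learning for Multichannel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised representation learning for multichannel EEG
    emotion recognition in which pairwise Granger-causality tests drive both
    a directed graph augmentation consumed by a residual graph-convolutional
    encoder (spatial branch) and an attention mechanism over sliding windows
    (temporal branch). Frequency-domain top-K denoising manufactures temporal
    positive pairs and same-video cross-subject sampling manufactures spatial
    positive pairs for an InfoNCE objective. Includes a synthetic session
    generator with known directed vector-autoregressive coupling for
    validation, network-recovery diagnostics, five-fold cross-validated
    fine-tuning, and a noise-perturbation evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
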