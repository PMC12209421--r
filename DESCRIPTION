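Package: fingerbci
Title: Simulated Closed-Loop EEG Decoding of Individual Finger Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying noninvasive brain-computer interfaces that drive
    a robotic hand at the level of individual fingers. Provides a seeded
    generator of synthetic sensorimotor EEG sessions with class-specific
    event-related desynchronization, the online preprocessing chain (common
    average reference, polyphase resampling, causal Butterworth filtering,
    sliding-window z-scoring), a compact convolutional EEG classifier with
    training, cross-session fine-tuning and gradient saliency maps, a filter
    bank common spatial patterns decoder with LDA, a closed-loop session
    simulator with probability smoothing and a flexion-accumulation decision
    rule, evaluation metrics (majority-vote accuracy, label shifts, all-hit
    ratio), and electrophysiological analyses (Morlet-wavelet ERD topographies
    and movement-related cortical potentials).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    MASS,
    signal,
    jsonlite,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
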