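Package: pulseseg
Title: Systolic and Diastolic Phase Segmentation of Wrist Pulse Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-period segmentation of radial (wrist) pulse waveforms into
    systolic and diastolic phases. Provides a seeded synthetic pulse-waveform
    simulator covering seven traditional-pulse morphologies with exact ground
    truth, signal preprocessing (zero-phase 20 Hz low-pass smoothing and
    sym8 wavelet baseline-wander removal), LabelMe-dialect annotation parsing
    with pixel-to-sample mapping, a bidirectional LSTM sequence labeller
    trained with Adam (implemented in compiled code), a slope-sum-function
    onset/notch baseline with adaptive thresholding, boundary-tolerance
    evaluation reports, and an end-to-end experiment runner.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
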