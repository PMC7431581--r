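Package: cpvi
Title: Sample Entropy Detection of Complex Patient-Ventilator Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects complex patient-ventilator interactions (CP-VI) --
    respiratory-rate shifts and clusters of asynchronous breaths -- from
    mechanical-ventilator airway flow and pressure waveforms. Computes
    Sample Entropy over sliding windows of the decimated signals, smooths
    the series with an exponential moving average, derives per-segment
    mean/maximum features, and flags segments whose percent change from
    the patient's own running-minimum baseline exceeds a threshold.
    Includes Matthews-correlation-based repeated holdout optimization of
    the embedding dimension, tolerance and threshold, performance metrics
    (sensitivity, specificity, predictive values, accuracy, MCC, Fleiss'
    kappa), and a synthetic ventilator waveform generator with ground
    truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
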