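Package: seizecast
Title: Patient-Specific Seizure Prediction with Autoencoder Transfer Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end scalp-EEG seizure prediction pipeline: synthetic EEG
    simulation with a controllable preictal signature, signal preprocessing
    into validity-masked 10-second windows, seizure-horizon (SOP/SPH)
    labelling and chronological splits, a deep convolutional autoencoder
    whose frozen encoder seeds patient-specific BiLSTM predictors (standard
    versus transfer-learning training), gap-aware firing-power alarm
    generation with a refractory period, and evaluation via seizure
    sensitivity, refractory-corrected false prediction rate, surrogate
    chance-level analysis, and paired Wilcoxon comparison of approaches.
    Neural networks are implemented natively with BLAS-backed matrix
    operations, so the package has no external deep-learning dependency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
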