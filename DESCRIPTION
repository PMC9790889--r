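Package: eegclfcnet
Title: Motor-Imagery EEG Classification with Filter-Bank CSP and a
    Compact Fuzzy Convolutional Recurrent Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for four-class motor-imagery EEG
    classification. Implements multi-scale filter-bank common spatial
    patterns (band-pass filter bank, per-window CSP via generalized
    eigendecomposition, variance features), Hilbert-envelope feature
    extraction with unified-length resampling, and EEG-CLFCNet: a compact
    depthwise/separable convolutional network followed by an LSTM stage
    and a fuzzy neural block with Gaussian rule memberships, trained by
    backpropagation with between-epoch fuzzy c-means centroid refresh.
    Includes a synthetic motor-imagery session generator with known
    spatio-spectral class structure, stratified cross-validation with
    Cohen's kappa, per-channel and per-region evaluation, and
    hyperparameter tuning by coordinate descent and Gaussian-process
    Bayesian optimization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
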