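Package: tvlnet
Title: Time-Varying Loudness Modelling and Neural-Network Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reference implementation of the time-varying loudness (TVL)
    pipeline of Glasberg and Moore (outer/middle-ear filtering, excitation
    patterns on the ERB_N (Cam) scale, compressive specific loudness, and
    attack/release temporal smoothing), together with a fast multilayer-
    perceptron surrogate trained by knowledge distillation to emit
    instantaneous loudness level in phons from a 61-band short-term
    spectrum. Includes a calibrated 16-kHz spectral front-end, seeded
    synthetic-sound and corpus generators (tones in noise, bandpass and
    notched noises, speech-like surrogates), an Adam-based training loop,
    and an evaluation suite with A-weighted-level and stationary-loudness
    baselines.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
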