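Package: ssvepnet
Title: Filter-Bank Complex-Spectrum Decoding of Steady-State Visual Evoked Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes steady-state visual evoked potential (SSVEP) EEG epochs
    with a filter-bank complex-spectrum convolutional network: multi-channel
    epochs are decomposed into sub-bands by zero-phase Chebyshev Type I
    band-pass filters, transformed to concatenated real/imaginary FFT
    features, and classified by a compact two-convolution-layer network
    trained with Adam. Includes a coordinate-wise three-candidate
    hyperparameter search (artificial gradient descent) with grid update
    rules, clamping and correlation diagnostics; a canonical correlation
    analysis (CCA) baseline with sinusoidal harmonic reference templates;
    and a seeded synthetic SSVEP generator emulating standard 12-target and
    40-target stimulus layouts so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    R.matlab
Config/testthat/edition: 3
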