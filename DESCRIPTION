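Package: sepsnet
Title: Accelerated Pure Shift NMR Reconstruction with a Squeeze-and-Excitation Residual Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for fast pure shift NMR spectroscopy under non-uniform
    sampling (NUS). Provides a physics-driven simulator of chunked
    interferogram pure-shift free induction decays (Lorentzian singlet
    mixtures, chunk-wise undersampling, additive noise, Fourier processing),
    a lightweight one-dimensional residual convolutional network with
    squeeze-and-excitation channel attention that maps undersampled real
    spectra to artifact-free fully sampled spectra, an iterative
    soft-thresholding (IST-S) compressed-sensing baseline, and quantitative
    evaluation utilities (RMSD, peak picking and matching, peak-intensity and
    integral correlation). The network, its training loop and its exact
    parameter and multiply-add accounting are implemented natively.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    optparse,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
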