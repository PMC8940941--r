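Package: fiberdl
Title: Deep-Learning-Assisted High-Speed Two-Photon Fiberscopy Image Restoration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and restoration toolkit for high-speed spiral-scanning
    two-photon fiberscopy. Generates synthetic neuron phantoms with GCaMP-like
    calcium transients and dwell-time-dependent shot noise, models the
    spiral-scan frame-rate/density trade-off including radial down-sampling,
    and restores fast low-density acquisitions with a two-stage conditional
    GAN (a denoising network whose outputs serve as intermediate ground truth
    for a joint denoising and inpainting network). Includes the evaluation
    suite used to quantify restoration quality and calcium-signal fidelity:
    SNR in dB, per-neuron and per-image normalized root-mean-square error,
    multi-scale structural similarity, and peak-normalized dF/F traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    tibble,
    generics,
    ggplot2,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
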