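Package: carsdelin
Title: Tumor Margin Delineation from Multimodal Nonlinear Microscopy
Version: 0.1.0
Authors@R: person("carsdelin", "maintainers", email = "carsdelin@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for tissue typing at breast tumor
    margins from multimodal nonlinear microscopy mosaics: hyperspectral
    coherent anti-Stokes Raman scattering (CARS) stacks over the
    high-wavenumber window (2700-3200 1/cm) combined with second harmonic
    generation (SHG) and two-photon fluorescence (TPF) channels. Provides a
    labeled synthetic phantom generator; the acquisition correction chain
    (ADC offset subtraction, beam-power calibration, fourth-order polynomial
    flat-field correction, mosaic stitching, 4x4 block averaging); constrained
    multiclass SVM recursive feature elimination and occurrence-voted
    sequential forward selection of wavenumbers; a ten-member pairwise
    linear-SVM ensemble with majority voting and per-sample cancer/healthy
    calls; and reporting utilities (multiclass and binary Matthews
    correlation, confusion matrices, class-mean spectra, intensity
    histograms, class-map and composite rendering). A compact linear SVM
    (squared-hinge, dual coordinate descent) is implemented in C++.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
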