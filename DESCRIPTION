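Package: flimphasor
Title: Phasor Analysis of NADH Fluorescence Lifetime Imaging
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Fit-free phasor (polar plot) analysis of time-correlated single
    photon counting (TCSPC) fluorescence lifetime image stacks of endogenous
    NADH. Provides a forward simulator for multi-exponential TCSPC decays
    (periodic excitation folding, Gaussian instrument response, early-bin
    truncation, Poisson photon noise), the standard preprocessing chain
    (median filtering, vessel masking, sliding-window decay binning with a
    photon-count floor), calibrated multi-harmonic phasor coordinates,
    bivariate dispersion summaries (standard deviational ellipses) and
    two-sample Hotelling T-squared separability tests of pharmacological
    condition clusters against baseline, and statistical classification of
    metabolic disruptions (LDA, KNN, naive Bayes) on the three-feature space
    of phasor coordinates and relative intensity change, with K-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    e1071,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
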