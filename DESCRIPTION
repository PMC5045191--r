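Package: nlhebb
Title: Nonlinear Hebbian Learning and Receptive-Field Formation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator and analysis toolkit for nonlinear Hebbian plasticity.
    Composes neuronal f-I curves with synaptic plasticity nonlinearities into
    effective Hebbian nonlinearities, quantifies their ability to learn
    kurtotic (long-tailed) features through a projection-pursuit objective and
    a selectivity index, learns receptive fields from whitened patch ensembles
    with single neurons or laterally inhibited networks with anti-Hebbian
    decorrelation, reduces triplet spike-timing dependent plasticity to its
    rate-domain quadratic form, and fits learned weights with Gabor functions.
    Includes synthetic generators (kurtotic generative patches, complex-cell
    energy representations, gammatone spectrogram segments) so every analysis
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png,
    tiff
Config/testthat/edition: 3
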