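Package: cellcull
Title: In Silico Laser-Scanning Purification of Adherent Stem Cell Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation toolkit for indirect laser-mediated
    elimination of unwanted cells in adherent culture. Generates synthetic
    phase-contrast and fluorescence frames of hiPSC colonies containing
    spontaneously differentiated patches, trains a patch-based convolutional
    classifier with two-round hard-example mining, renders per-pixel
    differentiation probability maps, plans gated high-speed laser raster and
    lattice scans with dose accounting, simulates the photothermal response of
    a light-responsive polymer layer under a moving beam by explicit 2-D heat
    diffusion, applies a calibrated cell-kill rule, and scores the resulting
    purity of undifferentiated cells as an in-silico analogue of a TRA1-60
    flow-cytometry readout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
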