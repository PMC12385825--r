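Package: gaffuse
Title: Gramian Angular Field Feature-Fusion Networks for VIS-NIR Spectral
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies two-class VIS-NIR transmittance spectra (e.g. seedless
    versus seeded watermelon cultivars) by encoding each 1-D spectrum as 2-D
    Gramian Angular Summation/Difference Field (GASF/GADF) images and fusing
    both encodings in a dual-input convolutional neural network with
    Squeeze-and-Excitation channel attention. Includes competitive adaptive
    reweighted sampling (CARS) wavelength selection, Kennard-Stone sample
    splitting, PLS-DA / RBF-SVM / 1-D CNN baselines, confusion-matrix metrics,
    PCA and t-SNE projections, sampling-Shapley wavelength attribution, a
    seeded synthetic-cohort generator, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    png,
    stats,
    graphics,
    grDevices,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
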