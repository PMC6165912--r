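Package: parotidseg
Title: Valid-Convolution U-Net Segmentation of the Parotid Gland in CT
Version: 0.1.0
Authors@R: person("parotidseg", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for automatic segmentation of the parotid gland, an
    organ at risk in head-and-neck radiotherapy planning, from CT volumes.
    Implements a family of three-resolution-level valid-convolution U-Nets
    (2-D single view, 2-D orthogonal-view ensemble with majority voting,
    and 3-D patch-based), together with two class-balancing training
    strategies (region-of-interest slice sampling and controlled
    minibatch composition of foreground-overlapping patches), soft Dice
    loss optimisation on CPU, tiled full-volume inference, largest
    connected-component postprocessing, and an evaluation suite with the
    Dice coefficient, a signed average surface distance in millimetres,
    and Wilcoxon signed-rank comparisons. A synthetic CT phantom
    generator with exact ground-truth masks makes the whole pipeline
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
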