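Package: dicecast
Title: Learning-Curve Forecasting and Training-Data Sufficiency for
    Biomedical Image Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how much training data a biomedical segmentation
    model needs. Trains a depth-parameterized family of residual U-Nets
    (2D and 3D) over a grid of dataset fractions, records learning curves
    of segmentation metrics (Dice, IoU, recall, precision), fits recurrent
    (LSTM) forecasters and a linear baseline to observed curve prefixes to
    predict the remainder of each curve, and reports the minimal data
    ratio achieving a target Dice score together with the point of
    diminishing returns. Includes synthetic 2D/3D segmentation tasks and a
    parametric learning-curve simulator so the full pipeline runs at desk
    scale without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    RNifti,
    yaml,
    stats,
    tools,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
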