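Package: landet
Title: Anatomical Landmark Detection and Spinopelvic Measurement from
    Lateral Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects anatomical landmarks on lateral spine and pelvis
    radiographs by treating each landmark as a small bounding-box object
    in a dense, anchor-based detection grid, and derives the five
    standard spinopelvic sagittal-alignment measures (sacral slope,
    pelvic tilt, pelvic incidence, lumbar lordosis and sagittal vertical
    axis) from the detected landmarks by exact 2-D geometry.  Training
    uses a multi-task loss whose objectness, box and class terms are
    augmented by physics-informed pairwise geometric constraints between
    landmarks.  A parametric synthetic-radiograph generator with exact
    ground truth supports training and evaluation without clinical
    images, and the package provides the field's standard agreement and
    accuracy statistics (relative RMSE and accuracy, MAE, Pearson
    correlation, single-rating consistency ICC, mean average precision,
    detection rate).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    png
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
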