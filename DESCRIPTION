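Package: pigwt
Title: Pig Live-Weight Estimation from Top-View Segmentation Masks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the live weight of fattening pigs from top-view binary
    segmentation masks. Implements the downstream stages of a mask-based
    morphometric pipeline: morphological cleanup of instance-segmentation
    masks, six shape features (area, perimeter, minimum-area-rectangle body
    length and hip width, moment-ellipse eccentricity, background deviation),
    a camera-to-back depth feature, a gradient-boosted feature-correction
    stage that compensates for body bending, and a three-strategy ensemble
    regression framework with native regression-tree, random-forest and
    Newton-boosting learners plus a ten-method baseline registry. Ships a
    synthetic top-view pig generator (biometry sampling calibrated to herd
    statistics, capsule bodies bent along circular arcs, pinhole camera
    scaling) so the whole pipeline is testable without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    e1071,
    glmnet,
    nnet,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
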