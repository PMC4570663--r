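Package: soilrtk
Title: Regression-Tree Kriging of 3D Soil Element Distributions from
    Correlative CT and SEM-EDX Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds micro-scale 3D maps of chemical elements inside a soil
    volume from two complementary imaging modalities: a 3D X-ray
    micro-computed-tomography grayscale volume and 2D SEM-EDX elemental
    count maps measured on physical cut faces.  Provides correlation-based
    registration of each 2D face as a (possibly tilted) staircase plane
    inside the CT volume, regression-tree trend modelling of element
    concentration on CT grayscale, isotropic variogram estimation with
    nested-model weighted-least-squares fitting and AIC selection, an
    ordinary-kriging solver with kriging variance, a two-layer sampling-grid
    optimizer that minimizes the kriging variance, and an end-to-end
    regression-tree-kriging predictor with leave-middle-layer-out
    cross-validation.  A synthetic-data generator with known ground truth
    (phase-structured volumes, step-function trends, Gaussian random
    residual fields by circulant embedding) makes every step testable
    without access to instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    png,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
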