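Package: bayestfm
Title: Bayesian Traction Force Estimation from Sparse Bead Displacements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell traction force fields from sparse fluorescent-bead
    displacements in traction force microscopy (TFM). Implements a Bayesian
    estimator whose force prior depends on the individual cell boundary: force
    magnitude decays with inward distance from the boundary and force
    direction is the inward gradient of a mean-curvature-flow smoothed
    level-set representation of the cell outline. Local direction and
    magnitude corrections are optimized jointly with the forces by coordinate
    ascent on the posterior. Includes the Boussinesq-Green elastic half-space
    forward model, ridge and lasso baselines with bead-wise cross-validation,
    a synthetic benchmark generator (model cell boundaries, sparse inward
    traction, random beads, Gaussian observation noise), and ROC/DTM/DTMB
    evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml,
    EBImage,
    png,
    tiff
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
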