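Package: surfmorph
Title: Landmark-Free Statistical Shape Analysis of Muscle Surface Meshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Generalized Procrustes surface analysis (GPSA) for triangulated
    anatomical surfaces without landmark correspondence: symmetric Procrustes
    surface metric, iterative-closest-point superimposition with prototype
    averaging, principal coordinates ordination of interspecimen distances,
    theoretical extreme-shape reconstruction with per-vertex variation heat
    maps, and general linear modelling of shape scores against participant
    covariates with backward stepwise reduction and partial r-squared. Includes
    a synthetic generator of muscle-like fusiform surface populations with
    known latent shape factors for validation, mesh readers and writers for
    PLY, STL, OBJ and legacy VTK, and a scriptable end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
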