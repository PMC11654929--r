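Package: dwellmap
Title: Model-Based Geostatistical Mapping of Housing Construction Materials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping the prevalence of improved dwelling construction
    materials (floors, walls, roofs) from two-stage cluster household surveys.
    Implements a material classification schema with a binary improved or
    unimproved recode, probability-proportional-to-density georeferencing of
    survey clusters to gazetteer settlements, confidentiality displacement of
    coordinates, exploratory semivariogram diagnostics of Pearson residuals,
    a latent Gaussian spatial logistic model with a Matern field approximated
    by a sparse precision matrix on a triangulated mesh and fitted by Laplace
    approximation, gridded prevalence prediction with posterior-draw standard
    errors and k-nearest-neighbour pixel imputation, GeoTIFF export, and
    multiclass evaluation metrics with macro and weighted averaging. A
    synthetic-world generator simulates surveys with known ground truth so
    the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Matrix,
    geosphere,
    mgcv,
    yaml,
    readr,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    pROC,
    tiff,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
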