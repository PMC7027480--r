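Package: ogdex
Title: Old-Growth Index Modeling of Forest Structural Development from
    Climate and Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes a composite old-growth structural index from forest
    inventory tree lists, fits a hierarchical Bayesian varying-slope model
    that links the rate of structural development to climatic and
    topographic covariates via Gibbs sampling with Gelman-Rubin convergence
    checking, and inverts the fitted model to map the stand age required to
    reach a target index value on raster grids. Includes terrain
    derivatives from digital elevation models (Horn slope, positive
    openness, D8 flow accumulation, potential solar radiation), an
    epsilon-adjusted logit transform for proportion responses, holdout
    cross-validation, a parameter-recovery harness, and a synthetic
    inventory-like data generator so the whole pipeline runs without
    restricted inventory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
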