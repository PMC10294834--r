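Package: sdmrisk
Title: Random-Forest Species Distribution Models and Snakebite Risk Overlay
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds presence/pseudo-absence random-forest species
    distribution models for pit vipers (Gloydius spp.), derives terrain
    covariates (slope, topographic position index) from a digital elevation
    model, screens collinear predictors by pairwise correlation and
    univariate deviance explained, thresholds suitability surfaces into
    binary habitat maps by maximising sensitivity plus specificity, unions
    them into a composite potential-habitat map, and computes downstream
    snakebite-risk statistics: regional incidence correlation, national-park
    habitat ratios, hiking-trail overlap, and land-cover composition. A
    synthetic-landscape generator reproduces the statistical structure the
    analysis assumes (elevation-temperature and herbaceous-shrubland
    collinearity, valley- and slope-driven species responses, Poisson
    regional incidents) so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    mgcv,
    randomForest,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
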