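Package: hybridrange
Title: Climate-Change Shifts in Range Overlap Between Garden Plants and
    Their Wild Congeners
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An ensemble species distribution modelling (SDM) workflow for
    asking whether climate warming changes the geographic overlap of
    climatically suitable ranges between not-yet-naturalized alien garden
    plants and their congeners in the resident flora.  Provides a
    synthetic-world generator (gradient-structured bioclimatic grids,
    additive warming scenarios of graded severity, and genus-structured
    virtual species with known Gaussian niches), occurrence cleaning to one
    record per grid cell, two pseudo-absence designs (10,000 random
    background points for regression models; occurrence-matched points
    outside a 200 km exclusion radius, replicated, for machine-learning
    models), four SDM algorithms (GLM, GAM, boosted regression trees and a
    random forest built on an internal weighted CART learner), repeated
    split-sample evaluation by the true skill statistic (TSS), TSS-weighted
    family ensembles thresholded at maximum TSS, conservative consensus
    binary maps, pairwise TSS and cell-count range overlap, and
    log-ratio intercept tests with a genus random effect.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
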