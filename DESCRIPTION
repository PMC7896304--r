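Package: borderniche
Title: Ensemble Climatic-Niche Models and Transboundary Range-Shift Accounting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates virtual-species worlds with known Gaussian climatic
    niches and runs an end-to-end ensemble species distribution modelling
    pipeline on them: presence rasterisation and pseudoabsence sampling
    constrained to zoogeographic realms, systematic predictor-subset selection
    (class balance, collinearity and AIC quartile-tally filters), spatially
    blocked cross-validation over ecoregion fragments, a four-family model
    ensemble (polynomial logistic regression, penalised thin-plate splines,
    random forests and boosted trees) with AUC-weighted projection under
    current and future climates, national aggregation of projected richness
    change against governance, GDP and emissions covariates, and
    border-by-border accounting of range bisection, cross-border range shifts
    and barrier-blocked species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    mgcv,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
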