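Package: nestipm
Title: Integrated Population Models and Transient LTREs for Hole-Nesting Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian integrated population models (IPMs) to breeding-survey,
    mark-recapture and population-count data from nestbox-breeding migratory
    passerines such as the pied flycatcher. The model combines an age-structured
    female-based projection with a Cormack-Jolly-Seber mark-recapture likelihood,
    generalized linear mixed models for reproduction, environmental covariates
    built from daily weather in phenology-anchored windows, and estimation of
    immigration. Posterior samples feed transient life-table-response-experiment
    (LTRE) decompositions of short- and long-term population growth into
    vital-rate, immigration and population-structure contributions, including
    real-time elasticities. A synthetic-data generator produces complete,
    statistically faithful datasets for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
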