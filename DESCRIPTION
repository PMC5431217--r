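Package: betadep
Title: Temporal Beta Diversity, Null-Model Departure and Drivers of
    Community Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying year-to-year variability of ecological
    communities sampled repeatedly at fixed sites. Computes observed
    temporal beta diversity as mean Bray-Curtis dissimilarity between
    consecutive years on log(x+1)-transformed abundances, contrasts it
    with a marginal-preserving quantitative null model (curveball
    presence shuffling followed by random re-allocation of individuals)
    to obtain the standardized departure statistic beta_dep, derives
    streambed disturbance and habitat covariates from field-style
    records, and relates both responses to environmental predictors by
    exhaustive-subset least-squares regression with AICc-based
    multimodel inference and Akaike-weight variable importance. A
    synthetic-data generator with separable deterministic
    (species-identity-dependent persistence) and stochastic
    (identity-free immigration) channels supports end-to-end testing
    and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
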