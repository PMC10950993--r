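Package: morantx
Title: Moran Birth-Death Models of Tumour Growth, Resistance and Treatment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time Moran birth-death models of a fixed-size cell
    population containing healthy, cancerous and drug-resistant mutant clones.
    Provides an exact stochastic simulator with fitness-weighted reproduction,
    driver mutation and time-varying treatment efficacy (constant-window and
    pharmacokinetically waning doses), a deterministic conditional-expectation
    recursion used as a fast surrogate for ensemble means, experiment drivers
    for fixation and stochastic-tunneling statistics and treatment-strategy
    comparisons, and a two-stage grid-search RMSE calibration of the model to
    tumour-growth time series. Includes a synthetic-data generator emulating
    weekly-dosed antibody treatment experiments so the full fitting pipeline
    can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
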