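Package: respdrift
Title: Diagnostics for Differential Non-Response over Time in Repeated
    Cross-Sectional Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A four-step framework for judging whether a declining and
    potentially more selective response over time has biased trends
    estimated from repeated cross-sectional health surveys. Step 1 models
    sociodemographic determinants of responding and subgroup-differential
    response trends from the sampling frame; step 2 tracks the variation
    (SD) of continuous outcomes per wave; step 3 contrasts
    post-stratification weighted and unweighted prevalence estimates; step
    4 follows per-wave logistic associations between outcomes and
    demographics. Results are condensed into a yes/no checklist with a
    summary verdict per outcome and subgroup dimension. A synthetic
    multi-wave survey simulator with known ground truth (declining
    response, subgroup-differential time trends, optional
    outcome-dependent selection, oversampling) supports validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
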