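Package: dexhaust
Title: Digital Exhaust from Zero-Interaction Home Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns contactless home-monitoring sensor streams (room-level
    passive-infrared motion, entrance and fridge door contacts, and an
    under-mattress bed sensor) into a comprehensive "digital exhaust":
    daily and nightly base measures, bi-weekly summary-statistic vectors
    (quantiles, iqr, mean, coefficient of variation, and the Kim-White
    robust skewness and kurtosis sk3/kr3), cosinor rest-activity rhythm
    parameters, and spectral measures. On top of the exhaust it builds
    machine-learning digital clinical outcome assessments (fall risk,
    frailty, depression, mild cognitive impairment) with gradient-boosted
    trees, participant-stratified resampling, soft voting, and
    SHAP-based global biomarker ranking. A synthetic-cohort simulator
    generates phenotype-linked sensor streams so the entire pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    zoo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
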