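Package: lockdownNO2
Title: Counterfactual Attribution of the COVID-19 Lockdown Effect on NO2 Pollution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the effect of an abrupt emission intervention (the early
    2020 COVID-19 lockdown in Chinese provincial capitals) on daily nitrogen
    dioxide concentrations by two routes: a per-city random-forest
    business-as-usual model driven by calendar and meteorological predictors,
    and a difference-to-difference estimator against the three preceding
    winters. Includes the model evaluation suite standard in air-quality
    work (index of agreement, normalized bias and error metrics), a
    log-linear concentration-response health impact assessment, a synthetic
    city-cohort generator with a known injected lockdown effect for
    end-to-end validation, and nearest-weather-station matching utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    geosphere,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
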