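Package: mortabridge
Title: Stochastic Mortality Models and Indicators for Abridged Life Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the logit Lee-Carter family of stochastic mortality models
    (LC, LC2, LCC, APC, RH, CBD, M8) to abridged life tables by binomial
    maximum likelihood, validates them with a hold-out scheme (RMSE, MAPE,
    standardized deviance residuals), forecasts period indices with
    random-walk-with-drift and AR(1) models, and computes and projects
    mortality indicators: life expectancy, modal age at death, the Lorenz
    curve of mortality and Gini indices on abridged tables. Includes a
    synthetic-data generator with known ground truth (sex-specific age
    profiles including a young-adult mortality hump, drifting period index,
    binomial death counts) for parameter-recovery and end-to-end testing,
    plus an end-to-end pipeline that writes a reproducible report bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
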