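Package: lagrisk
Title: Lagged Air-Pollution Exposure and Cancer Incidence Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the association between lagged annual-mean
    fine-particulate (PM2.5) exposure and regional cancer incidence rates, and
    for forecasting incidence from a panel of ten lagged exposure columns.
    Provides a synthetic region-year panel generator with autocorrelated
    exposure series and known lag weights; normality-gated Pearson/Spearman lag
    correlation and Deng grey relational analysis; multicollinearity
    diagnostics (correlation matrix, variance inflation factors, tolerance,
    eigenvalues and condition indices); three collinearity-robust predictors
    (ridge regression with ridge trace and ridge-adjusted VIF, support-vector
    regression with kernel selection and permutation feature importance, and a
    small three-hidden-layer ReLU network with node-count tuning); combination
    forecasts under standard-deviation, reciprocal-variance and
    optimal-weighting schemes; and forecast accuracy metrics (MAE, MSE, MAPE,
    Theil's U). A single driver runs the full pipeline reproducibly from a
    config and writes tidy CSV tables plus a JSON report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
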