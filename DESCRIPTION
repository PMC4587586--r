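Package: resicast
Title: Recursive Residual Correction for Univariate Time-Series Forecasting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: One-step-ahead forecasting of univariate series (typified by daily
    mean PM2.5/PM10 concentrations) by a base forecaster whose error series is
    recursively examined for remaining temporal structure. An autocorrelation
    white-noise gate decides whether residuals still carry signal; when they do,
    a further forecaster is trained on the residual series and its prediction is
    added to the final forecast. The base model is a hybrid system: a genetic
    algorithm searching lag count, hidden-layer size and training algorithm of a
    multilayer perceptron, scored by a composite fitness of six forecast metrics
    (MSE, MAPE, Theil's U, ARV, POCID, index of agreement), followed by an
    optional phase adjustment. Includes seeded synthetic-series generators,
    chronological splitting, min-max normalization, report rendering and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
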