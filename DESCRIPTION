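Package: littoralHDM
Title: Sampling-Design Evaluation for Littoral Habitat Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to evaluate how spatial survey design affects the accuracy of
    habitat distribution models along a one-dimensional coastline. Provides a
    data model for ordered chains of presence/absence survey points with
    environmental predictors, a synthetic-coastline generator with spatially
    autocorrelated gradients and calibrated habitat prevalences, train/test
    splitters for aggregated, interspaced and random sampling designs at
    fractions from 10 to 50 percent, binomial logistic model fitting with
    exhaustive AIC subset selection and explained deviance, and held-out
    evaluation via ROC AUC, the threshold maximizing sensitivity plus
    specificity, and confusion-matrix statistics, together with an orchestrator
    that runs the full habitat-by-scenario experimental grid and null-model
    replicates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    readxl,
    pROC,
    withr
Config/testthat/edition: 3
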