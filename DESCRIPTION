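Package: varselbench
Title: Benchmarking Variable-Selection Methods for QSAR/QSPR Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Implements and benchmarks five variable-selection methods for
    regression on molecular-descriptor and spectral tables: LASSO, genetic
    algorithm based partial least squares (GAPLS), genetic algorithm based
    support vector regression (GASVR), Boruta, and r-Boruta (Boruta with a
    chance-correlation-calibrated percentile threshold). Selections are
    evaluated with a three-metric protocol: the 10th-percentile mean absolute
    error across a 24-configuration regression suite, the proportion of
    original variables selected, and the proportion of spiked uniform random
    probe variables selected. Includes a synthetic-data generator with known
    informative structure so every stage can be validated without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    ranger,
    e1071,
    rpart,
    nnet,
    xgboost,
    mixOmics,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    yaml,
    optparse
Config/testthat/edition: 3
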