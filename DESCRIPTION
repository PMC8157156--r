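Package: crashsev
Title: Injury-Severity Modelling and Cost-Based Evaluation for Multi-Vehicle Crashes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing and predicting injury severity in
    multi-vehicle crashes. Implements the random-parameters (mixed) logit
    model with heterogeneity in means and variances, estimated by simulated
    maximum likelihood over Halton draws; likelihood-ratio tests for
    temporal stability of crash models across years; a bagged decision-tree
    (random forest) prediction baseline with learning-curve tree-count
    selection and stratified cross-validation; and a comprehensive-crash-cost
    evaluation framework that scores classifiers by the economic and
    quality-adjusted-life-year cost of their errors rather than raw accuracy.
    A synthetic crash-data generator with known ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
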