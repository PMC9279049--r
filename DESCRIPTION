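Package: deeppsy
Title: Multimodal Behavioral Screening of Student Mental-Health Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Digital-phenotyping pipeline for screening boarding-school
    students at elevated mental-disorder risk from routine behavioral logs.
    Implements bespoke feature engineering (dining-regularity entropy,
    k-means cluster-distance anomaly scores, grade-point transforms, an
    insomnia statistic), a small convolutional network over day-by-hour
    internet-activity grids, a five-algorithm classifier bench, and the
    DeepPsy fusion model (CNN plus LSTM trajectory branch concatenated with
    a fully connected branch over tabular features), together with a seeded
    synthetic-cohort simulator with planted effect sizes and experiment
    drivers for paired model comparison, feature ablation and
    hyperparameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    rpart,
    nnet,
    e1071,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml,
    knitr,
    rmarkdown
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
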