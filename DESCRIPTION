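Package: ptsarank
Title: Disease Prioritization for Psychological Trauma and Social
    Avoidance via Graph-Convolutional Encoding and Gradient Boosting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes diseases likely to cause psychological trauma and
    social avoidance (PTSA) from gene functional networks and disease-protein
    annotations.  Computes best-match-average disease similarity from a
    log-likelihood-scored gene interaction network, assembles a labeled
    disease graph with binary protein features, encodes nodes with a spectral
    graph convolutional network, classifies them with a from-scratch
    second-order gradient-boosted tree ensemble, and evaluates by
    leave-one-positive-out cross-validation with ROC-AUC and
    average-precision AUPR.  Includes a synthetic scenario generator with
    planted class structure, scoring rules for the Social Avoidance and
    Distress Scale and the Rosenberg Self-Esteem Scale, and summary-statistic
    tests (one-sample t from printed summaries, Pearson chi-square).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
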