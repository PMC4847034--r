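Package: dfqsar
Title: Decision Forest Consensus Models for QSAR Binary Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates Decision Forest consensus classifiers for
    quantitative structure-activity relationship (QSAR) modelling of binary
    endpoints such as rat alpha-fetoprotein (AFP) binding. A Decision Forest
    combines several Gini-index classification trees grown on mutually
    exclusive molecular-descriptor subsets; the consensus probability, its
    0.5 call threshold and a |p - 0.5|/0.5 prediction confidence are exposed
    alongside descriptor-table preprocessing (constant-column removal,
    min-max scaling), repeated k-fold cross-validation, label-permutation
    (y-scrambling) null testing, confidence-binned accuracy profiles,
    permutation-background informative-descriptor identification, and a
    synthetic descriptor-matrix generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
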