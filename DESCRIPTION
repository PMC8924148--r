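Package: damda
Title: Dimension-Adaptive Mixture Discriminant Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Model-based discriminant analysis for test data containing
    classes absent from the training sample and extra variables recorded
    only at prediction time. An eigenvalue-decomposition discriminant
    classifier (EDDA) is learned on labelled data; a discovery-phase EM
    algorithm then detects hidden classes in the unlabelled test set and
    extends the learned Gaussian parameters to the enlarged variable
    space by inductive conditional estimation with fixed marginal
    distributions. Includes BIC selection of the number of hidden
    classes, inductive stepwise variable selection, evaluation metrics,
    a synthetic-data generator for class-generative/correlated/noise
    variable designs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mclust,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
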