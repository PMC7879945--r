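Package: invsel
Title: Feature Selection Under Erroneous Sample Classifications
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection and model building for high-dimensional data
    when the sample classification itself is error prone (noisy human ratings,
    binary or semi-quantitative). Implements an inverted-role pre-filtering
    heuristic (per-feature likelihood-ratio screening with the classification
    as predictor, multiplicity adjustment, and cross-validation on the inverted
    roles), a standard cross-validation baseline, backward stepwise model
    building under AIC, BIC or cross-validation error, AUC-based evaluation
    against a known ground truth (binary and Hand-Till style multiclass), and a
    seeded simulation benchmark that injects Bernoulli classification errors
    into normally distributed grouped data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
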