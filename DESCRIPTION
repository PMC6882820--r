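Package: pcsnet
Title: Sparse Gaussian Graphical Models with Partial Correlation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of sparse Gaussian graphical models from
    multivariate data, with a two-stage partial correlation screening
    (PCS) procedure that controls the false positive rate of the
    recovered network. Provides four base estimators (graphical lasso,
    l1-regularized nodewise regression with AND/OR edge rules, joint
    sparse regression (SPACE), and nodewise ridge regression), eleven
    regularization tuning rules (K-fold cross-validation with minimum
    and one-standard-error selection, likelihood and prediction-error
    losses, BIC, extended BIC, and finite-sample penalty levels), and
    the cross-validated thresholding step that screens estimated
    partial correlations. Includes generators for standard benchmark
    population models (chain graphs, nearest-neighbor graphs, random
    graphs), a replicated simulation driver reporting true and false
    positive rates, a rank-based Gaussian copula (nonparanormal)
    transform, and a multi-network combination rule.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    jsonlite,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
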