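Package: rotboost
Title: Rotation-Based Boosted Tree Ensembles for Gene Expression Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying gene expression profiles with rotation-based
    tree ensembles. Implements RotBoost (a Rotation Forest whose per-rotation
    base learner is an AdaBoost ensemble of classification trees), plain
    Rotation Forest, AdaBoost.M1, bagging and single-tree baselines, with
    per-subset PCA or FastICA rotations. Includes fast correlation-based
    filter (FCBF) gene selection built on MDL discretization and symmetric
    uncertainty, a generalized signal-to-noise-ratio gene ranker, microarray
    preprocessing (gene-wise mean imputation and standardization), balanced
    0.632 bootstrap error estimation, kappa-error ensemble diversity
    diagnostics, paired t-test method comparison, and a synthetic microarray
    generator with planted informative and redundant genes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    jsonlite,
    rpart,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
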