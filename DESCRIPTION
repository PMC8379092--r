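Package: nestedSLR
Title: Nested Lasso Feature Selection and Sparse Logistic Regression for
    Diffusion-Perfusion Imaging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discriminates vascular mild cognitive impairment from cognitively
    normal small-vessel-disease patients using atlas-wise diffusion (FA/MD/AD/RD
    over ICBM-DTI-81 white-matter labels) and perfusion (CBF over AAL gray-matter
    labels) feature tables. Implements 10x10 nested lasso feature selection with
    stratified folds and pool-shared reduced feature sets, leave-one-out
    cross-validated L1-penalized (sparse) logistic regression, consensus
    discriminative-feature identification by selection frequency, ROC/AUC and
    McNemar paired-classifier comparison, and covariate-adjusted partial
    correlations between discriminative features and cognitive scores with
    Benjamini-Hochberg false-discovery-rate correction. Ships a synthetic cohort
    generator that plants configurable group differences and feature-cognition
    partial correlations so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    nortest,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
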