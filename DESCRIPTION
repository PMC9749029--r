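Package: cliffbench
Title: Activity-Cliff-Aware Benchmarking of Bioactivity Regression Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Curates compound bioactivity tables (replicate aggregation with
    Dixon's Q outlier screening, neutralization and canonicalization of SMILES,
    stereo-duplicate removal), identifies activity-cliff compound pairs by a
    three-metric structural-similarity consensus combined with a potency-fold
    criterion, produces cliff-stratified train/test splits via spectral
    clustering of fingerprint similarities, trains descriptor-based baseline
    regressors (k-nearest neighbours, support vector machine, gradient
    boosting, random forest, multilayer perceptron) with fivefold
    cross-validated grid search, and evaluates them with overall RMSE and a
    cliff-restricted RMSE, including a PCA-based global ranking of methods.
    Molecular structure handling (canonical SMILES, extended-connectivity and
    MACCS fingerprints, 3D conformer generation) is delegated to Open Babel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    randomForest,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
SystemRequirements: Open Babel (the 'obabel' executable on the PATH)
Config/testthat/edition: 3
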