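Package: rncv
Title: Repeated Nested Cross-Validation with Permutation Tests for Small
    Binary-Classification Datasets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluation machinery for binary classifiers trained on small
    tabular datasets. Provides leakage-safe nested cross-validation with an
    inner stratified grid search over a support-vector-machine pipeline
    (mutual-information feature selection, standardisation, random
    oversampling), repeated nested cross-validation across random seeds, and
    a shared-permutation non-parametric test that attaches an empirical
    probability of the null hypothesis (no exploitable feature-label
    dependency) to every score. Eight evaluation metrics (accuracy, balanced
    accuracy, precision, recall, F1, Matthews correlation coefficient,
    Cohen's kappa, AUC) are supported for both model selection and
    evaluation, together with confusion-matrix averaging, a synthetic
    two-class Gaussian dataset generator, ensemble sweeps with bootstrap
    confidence intervals, and ablation studies of the pipeline components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
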