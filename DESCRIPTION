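Package: specopt
Title: Automated Spectral Preprocessing Pipeline Optimization for
    Chemometric Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for selecting spectral preprocessing pipelines for
    chemometric calibration by Gaussian-process Bayesian optimization.
    Enumerates valid ordered pipelines of scatter-correction, smoothing,
    derivative, baseline, scaling and dimensionality-reduction operators
    under incompatibility rules, scores candidate pipelines with a ridge
    regressor under group-aware cross-validation, and partitions samples
    with a replicate-aware Kennard-Stone algorithm so that replicate
    measurements never straddle the calibration/test divide.  Includes a
    second-stage harness tuning six standard regressors on the winning
    pipeline, paired statistical comparison of preprocessing conditions
    (Shapiro-Wilk gated paired t / Wilcoxon tests with Bonferroni
    control and Cohen's d), and a synthetic mid-infrared milk spectra
    generator with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    signal,
    splines,
    jsonlite,
    yaml,
    MASS,
    e1071,
    glmnet,
    xgboost,
    mixOmics,
    kernlab
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
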