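Package: boldmc
Title: Model Comparison for Correlated Parametric Regressors in BOLD GLMs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Disentangles highly correlated parametric regressors, such as
    the Rescorla-Wagner reward prediction error and the reward outcome, in
    event-related BOLD general linear model analyses. Provides a
    Rescorla-Wagner learning-trace generator, construction of HRF-convolved
    and z-standardized regressors with serial orthogonalization, ordinary
    least squares fitting with log-residual-variance and AIC/BIC summaries,
    three equivalent model-comparison procedures (orthogonalized betas,
    non-orthogonalized betas, residual variance of reduced models), and a
    ground-truth two-region BOLD simulator for validation, plus file I/O
    for BIDS-style event tables, TSV time series and NIfTI volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
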