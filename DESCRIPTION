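Package: GrowthCurveFit
Title: Growth-Curve Model Catalogue, Bounded Estimation and Data Management
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A desk-scale toolkit for fitting biological growth curves.
    Provides a catalogue of algebraic and differential growth models
    (Gompertz, Logistic, Richards, Baranyi, hyperbolastic type III,
    live-cell-fraction spheroid ODE, polynomial and exponential-decay
    baselines), automated box-constrained multi-start nonlinear least
    squares with RMSE-based model comparison, replicate-pooled fitting,
    manual log-linear regression, an extensible model registry with a
    two-function simulate/estimate plugin contract, a hierarchical
    project/experiment/measurement data store with CSV import/export,
    and a seeded synthetic-data generator for benchmarking parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
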