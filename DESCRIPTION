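Package: fcLasso
Title: Bootstrapped Cross-Validated LASSO Stability Selection for
    Brain-Behavior Association
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Links speech disfluency rates (repetitions, prolongations,
    blocks) in adults who stutter to resting-state ROI-to-ROI functional
    connectivity. Provides behavioral rate computation and cohort
    summaries, inter-rater intraclass correlation, Fisher-z connectivity
    tables built from ROI time series, an L1-penalized regression core
    solved by cyclic coordinate descent with cross-validated lambda
    selection, paired-bootstrap coefficient aggregation with
    Bonferroni-adjusted bootstrap-SE confidence intervals, stability
    selection with a first-drop cutoff, Levene-test site
    heteroscedasticity diagnostics, and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
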