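Package: glycodyn
Title: Self-Supervised Transformer Modelling of Continuous Glucose
    Monitoring Dynamics
Version: 0.1.0
Authors@R:
    person("Glycodyn", "Developers", email = "glycodyn@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling daily continuous glucose monitoring (CGM)
    profiles with a masked-token transformer encoder. Provides a synthetic
    CGM cohort simulator, CSV parsing and day segmentation onto the 288-slot
    5-minute grid, glucose tokenization over a 260-level vocabulary with
    TF-IDF-weighted adaptive masking, a 4-block/8-head encoder with
    masked-token pretraining and imputation benchmarking against linear and
    KNN baselines, supervised fine-tuning for glycemic-status screening,
    two-stage hierarchical subtyping of non-diabetic individuals with
    cosine-similarity assignment, a panel of glycemic variability metrics
    (MAGE, TIR, eA1C, HBGI, autoregressive order selection), and a gated
    recurrent postprandial glucose predictor with in-silico meal
    perturbation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
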