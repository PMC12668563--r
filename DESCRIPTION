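Package: ancestrylasso
Title: Ancestry-Aware Disease Prediction with Penalized Regression,
    Interaction Modeling and Lasso Pretraining
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ancestry-aware disease risk prediction with
    penalized regression on multiomic cohort data. Implements an L1-penalized
    logistic regression solver with per-observation offsets and per-feature
    penalty factors, a group-lasso interaction model with strong hierarchy
    (glinternet-style candidate pairs restricted to age, sex, ancestry and
    polygenic risk scores), and a two-stage pretrained lasso that transfers a
    pooled multi-ancestry fit to ancestry-specific models through an offset
    and penalty factors mixed by a parameter alpha. Includes a synthetic
    cohort generator emulating a biobank-style feature structure (imbalanced
    ancestries, correlated metabolite blocks, ancestry-separating genotype
    principal components, per-disease polygenic scores), ROC-AUC evaluation
    with one-sided DeLong tests for paired curves, a win-count binomial
    meta-analysis, and an end-to-end study pipeline comparing model families
    across All / Mix / ancestry-specific training sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
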