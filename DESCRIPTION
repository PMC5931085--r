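Package: heightmr
Title: Mendelian Randomisation of Adult Height and Ovarian Cancer Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for Mendelian randomisation of adult height on
    ovarian cancer risk using individual-level multi-study case-control data.
    Implements weighted genetic-risk-score instrument construction with SNP
    quality-control filters and sensitivity subsets, two-stage
    predictor-substitution MR with per-study logistic second stages,
    DerSimonian-Laird random-effects meta-analysis with heterogeneity
    statistics, MR-Egger pleiotropy regression, genetic-score confounder
    screens, closed-form statistical power for binary-outcome MR, and a
    synthetic multi-study cohort generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
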