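Package: mindrsa
Title: Distinctiveness of Mental-State Representations via Searchlight RSA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to measure how distinctly mental states are represented,
    for the self and for other people, in multivoxel fMRI activity patterns
    and in explicit similarity ratings. Implements searchlight and
    region-of-interest representational similarity analysis with a
    per-target distinctiveness statistic (mean pairwise Pearson correlation
    distance among state-specific patterns), group inference by paired
    t-tests and repeated-measures ANOVA with threshold-free cluster
    enhancement and maximal-statistic permutation control of the
    family-wise error rate, linear mixed-effects analysis of pairwise
    state-similarity ratings with Satterthwaite degrees of freedom and
    Nakagawa R-squared, and classical multidimensional scaling with
    Procrustes alignment for visualizing state geometry. A synthetic-data
    module generates condition-wise beta volumes, BOLD-like series, trial
    designs and rating tables with known ground truth for parameter
    recovery and error-rate validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    lme4,
    lmerTest,
    emmeans,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
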