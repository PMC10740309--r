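Package: sexvoldiff
Title: Robust Univariate and Multivariate Sex Differences in Regional Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for estimating sex differences and similarities in
    regional gray-matter volumes with and without adjustment for total
    intracranial volume (TIV). Implements the power-corrected-proportions
    (PCP) TIV adjustment, robust z-scoring, a five-part univariate battery of
    robust effect sizes (heteroscedastic rank test, distribution overlap,
    Harrell-Davis decile shift functions, Cliff's delta and probability of
    superiority, empirical Cohen's U3, interquartile-ratio and
    skewness/kurtosis comparisons), L2-penalized logistic regression with
    bootstrap optimism correction and nomograms, a projection-type
    multivariate Wilcoxon-Mann-Whitney analysis with the Q classification
    effect size, HC4 bootstrap-t correlations, and a synthetic allometric
    cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    sandwich,
    optparse
Config/testthat/edition: 3
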