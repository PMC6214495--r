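Package: methpanel
Title: Minimal DNA Methylation Biomarker Panels via Stability Selection
    and Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Selects small, diagnostically informative panels of CpG
    methylation sites from Illumina-style beta-value matrices. A staged
    pipeline combines a differential-mean (delta-beta) prefilter,
    stability selection with L1-penalised logistic regression on random
    sample subsets, random-forest impurity importances, an
    importance-threshold sweep scored by cross-validated cross-entropy
    loss (LogLoss), and a one-standard-error minimal-panel rule.
    Companion diagnostics cover correlated-site interchangeability,
    Kuncheva-index selection stability under bootstrap resampling,
    noise-injection robustness, LogLoss-based outlier flagging, and
    k-means heterogeneity clustering. A seed-deterministic synthetic
    cohort generator with planted differential, subtype-private and
    correlated sites supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
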