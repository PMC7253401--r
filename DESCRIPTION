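Package: hubscreen
Title: Hub-Gene Screening via Weighted Co-Expression Networks,
    Differential Expression and Survival Filters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-stage screen for tumor hub genes on gene-level
    expression cohorts: weighted gene co-expression network analysis
    (soft-threshold selection by scale-free topology fit, topological
    overlap, hierarchical module detection, module eigengenes, module
    membership and trait significance), empirical-Bayes moderated-t
    differential expression with trend-consistency filters and a
    tertile chi-square grade test, an expression-stratified survival
    screen (log-rank, Cox likelihood-ratio, mortality-rate ratio), and
    intersection of all result sets into a final key-gene report. A
    latent-factor synthetic cohort generator with planted ground truth
    supports end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    mclust,
    pROC,
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
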