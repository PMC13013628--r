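Package: maturityscreen
Title: Cross-Dataset Transcriptomic Maturity and Aging Signature Analysis
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening differential-expression signatures for
    hippocampal hyper-maturity and accelerated-aging phenotypes. Implements a
    directional, rank-based overlap statistic between signed DEG lists (a
    transparent, fully specified analogue of platform "Running Fisher" style
    tests), signed -log10 maturity/aging/excitation/suppression indices,
    polarity-adjusted Cohen's d anxiety effect sizes and their correlation
    with maturity, hypergeometric gene-set enrichment with Fisher-method
    meta-analysis, PCA-based grouping of models into enhanced-development
    versus accelerated-aging classes, cell-type contribution scoring of bulk
    aging signatures against single-cell DEG atlases, and a synthetic-data
    generator that plants known signature concordance so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
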