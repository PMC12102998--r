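Package: ptrskit
Title: Polygenic Transcriptome Risk Scores for Binary Disease Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates genetic risk scores for a binary disease
    phenotype from GWAS summary statistics: clumping-and-thresholding
    polygenic risk scores (PRS), tissue-specific polygenic transcriptome
    risk scores (PTRS) derived from summary-level transcriptome-wide
    association (S-PrediXcan-style) gene effects and predicted gene
    expression, weighted combined scores, and a clinical baseline model.
    Includes LD-aware summary-statistic harmonization and region-wide
    z-score imputation, a simplified MAGMA-style tissue enrichment test,
    covariate-adjusted concordance statistics with DeLong and bootstrap
    confidence intervals, paired ROC comparisons, and a liability-threshold
    cohort simulator with LD-structured genotypes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    yaml
Config/testthat/edition: 3
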