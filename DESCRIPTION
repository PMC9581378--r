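Package: liversig
Title: Liver Secretome Gene Signatures for NAFLD Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering candidate circulating biomarkers of
    non-alcoholic fatty liver disease (NAFLD) from liver biopsy RNA-seq.
    Implements negative-binomial Wald differential expression between
    NAFLD-activity-score (NAS) groups with median-of-ratios normalization,
    directional Stouffer gene-set analysis, liver-selectivity scoring by
    cross-tissue coefficient of variation, secretion-evidence filtering and
    candidate ranking, re-validation in independent cohorts, nonparametric
    cohort statistics (Kruskal-Wallis, Dunn post hoc, Spearman), and a
    seeded synthetic-data generator with planted ground truth for
    end-to-end benchmarking of the whole pipeline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
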