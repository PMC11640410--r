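Package: mirmeta
Title: Random-Effects Meta-Analysis of miRNA Expression and Downstream
    Target Integration for Drug-Resistance Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering drug-resistance
    associated microRNAs from several small two-group expression studies
    and tracing them to candidate genes. Per-study differential expression
    uses empirical-Bayes moderated t-statistics with Benjamini-Hochberg
    control; study-level log2 fold changes are combined per miRNA with a
    DerSimonian-Laird random-effects model after Cochran's Q heterogeneity
    assessment. Significant human miRNAs are mapped to validated target
    genes, intersected with differentially expressed genes from validation
    mRNA studies, and the resulting gene set is carried through
    hypergeometric over-representation analysis with kappa-score term
    grouping, protein-interaction hub ranking, and Kaplan-Meier/log-rank
    survival analysis. A synthetic-data module generates every input with
    planted signal so the whole pipeline is testable offline.
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
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    limma,
    withr,
    metafor,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
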