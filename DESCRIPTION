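Package: regionvuln
Title: Cell-Type Vulnerability to Disease Genes and Drug Targets from
    Regional Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline that maps brain-region (temporal versus
    frontal lobe) and cell-type-resolved gene expression onto neuropsychiatric
    GWAS genes, disease differential-expression signatures and psychoactive
    drug-target sets. Provides 10x-convention MatrixMarket and GMT readers, a
    negative-binomial synthetic-data generator with planted ground truth,
    quality-control filters and log-normalization, one-versus-rest marker
    detection by logistic regression, region-balanced negative-binomial
    differential expression (TMM normalization, empirical-Bayes dispersion,
    quasi-likelihood F-tests via edgeR), expression-aware hypergeometric
    gene-set enrichment, preranked gene-set enrichment analysis, Jaccard
    pathway networks, Spearman co-expression networks, and the per-cell-type
    vulnerability contrast between GWAS genes and drug targets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
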