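Package: epistasisr
Title: Case-Control SNP-SNP Epistasis Detection with MDR, Information
    Theory and Weighted Effect Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for detecting epistatic
    interactions between candidate SNPs in case-control designs: genotype
    QC (minor allele frequency, Hardy-Weinberg equilibrium), per-SNP
    inheritance-model selection from genotype odds ratios,
    information-theoretic interaction analysis (information gain, G-square,
    interaction information, Rajski-distance attribute dendrograms),
    from-scratch Multifactor Dimensionality Reduction with cross-validation
    and permutation testing, weighted-effect-coded logistic regression with
    interaction product terms, and ROC-based classifier evaluation.
    Includes a synthetic genotype generator with embedded two-locus
    penetrance models so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    vcfR
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
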