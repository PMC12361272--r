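Package: grskit
Title: Interaction-Aware Genetic Risk Scores for Type 1 Diabetes Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating HLA-interaction-aware genetic
    risk scores (GRS) from case-control genotype data. Provides synthetic
    cohort simulation with a DQA1-DQB1 haplotype pool, haplogenotype
    interaction effects and LD-tagged SNPs; SNP quality control (MAF,
    Hardy-Weinberg exact test, missingness) and per-variant logistic
    association with covariate screening, genomic inflation and fixed-effect
    meta-analysis; two-locus haplotype inference, frequency filtering and
    tag-SNP selection by r2 and D'; haplogenotype interaction modelling with
    multiplicative dose-product terms; ln(OR)-weighted score construction
    with interaction lookup; and discrimination evaluation (ROC AUC, PRAUC,
    paired and unpaired DeLong tests, centile cutoff tables, tertile
    stratification). The central entry point fit_cgrs() returns a classed
    model object with the usual print, summary, coef and predict methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
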