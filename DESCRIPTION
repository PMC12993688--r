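Package: microgwas
Title: Host-Genetics to Gut-Microbiome Association Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for microbiome genome-wide association
    studies: genotype quality control (call rate, heterozygosity, sex
    check, exact Hardy-Weinberg filtering, kinship, PCA outliers),
    compositional phenotype preparation with prevalence and core-abundance
    filters, rank-based inverse normal transformation, Shapiro-Wilk
    normality routing into quantitative or binary models,
    covariate-adjusted linear and logistic association scans with genomic
    control, phenome-wide scans over high-impact variants, gene-based
    principal-component regression tests, genotype-stratified
    quasi-Bayesian causal mediation with a frequency-matched SNP null and
    Z-difference flagging, and between-cohort composition comparison
    statistics. Includes synthetic cohort generators so the whole pipeline
    is exercised end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
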