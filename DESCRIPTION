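Package: oathr
Title: Reconstructing Association Study Results from Naive Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Least-squares reconstruction of genome-wide association study
    (GWAS) effect estimates, standard errors and p-values for any subset of
    covariates from naive summary statistics (NSS): the sample size together
    with the variance-covariance entries of phenotype, genotype and
    covariates. Provides NSS encoding from individual-level data (PLINK
    binary, dosage tables or VCF) with marker quality control, a plain-text
    NSS exchange format, genome-wide scans, exhaustive covariate-subset
    enumeration with Bonferroni hit calling and in-depth evaluation
    (p-value grouping and one-way F tests), genomic-control lambda
    computation and adjustment, inverse-variance fixed-effects meta-analysis
    of per-cohort NSS, and seeded simulators for structured genotypes,
    genetic relationship matrices, eigenvector covariates and phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
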