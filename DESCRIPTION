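Package: raresetburden
Title: Rare-Variant Gene-Set Burden Testing for Stratified Case-Control Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Case-control burden analysis of rare pathogenic and likely
    pathogenic (P-LP) coding variants across multi-stratum sequencing
    cohorts. Selects analysis variants by explicit rules (biallelic SNVs,
    minor-is-alternative, maximum population minor allele frequency below
    1 percent, protein-altering consequence, ACMG 2015 evidence-combining
    classification), fits Firth penalized logistic regression of case
    status on per-individual P-LP allele counts within each stratum,
    combines strata by the weighted Z-score method with inverse-variance
    pooled odds ratios and Holm multiplicity control, and validates
    gene-set signals with a Cochran-Mantel-Haenszel statistic calibrated
    against an empirical null of random gene sets. Includes a seeded
    synthetic cohort generator with configurable gene-set enrichment, a
    singleton-dominated allele-count spectrum and stratified population
    structure, plus polygenic risk score construction by LD clumping,
    p-value thresholding and dosage scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
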