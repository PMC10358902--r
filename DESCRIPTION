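Package: tgscore
Title: Total Genotype Score Analysis of Endurance Trainability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the association between a panel of single
    nucleotide polymorphisms (SNPs) and the response to an endurance training
    programme. Provides genotype panel input and quality control (probe
    orientation normalisation, replicate-call consistency filtering,
    monomorphic SNP removal), Cooper 12-minute run response phenotypes and
    session-RPE training loads, Hardy-Weinberg expected genotype frequencies
    with Fisher's exact comparison against population allele frequencies,
    a chi-square screen with ANOVA confirmation of favorable alleles, an
    additive 0/1/2 favorable-allele score regressed against percentage
    training response, group-comparison statistics with Cohen's d effect
    sizes, and a seeded synthetic cohort generator for parameter-recovery
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    car,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
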