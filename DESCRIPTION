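Package: gtseqpop
Title: Amplicon SNP Genotyping and Introgression Analysis for
    Hybridogenetic Water Frogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for GT-Seq (genotyping-in-thousands by
    sequencing) SNP panels in the hybridogenetic water frog complex
    (Pelophylax lessonae, P. ridibundus and their hybrid P. esculentus):
    coverage-threshold genotype calling from per-site base counts, IUPAC
    consensus sequences, taxon assignment from diagnostic read dosages,
    population pooling and allele-frequency estimation, species-specific
    SNP classification, introgression-rate estimation (per SNP, per
    population and overall), Kruskal-Wallis and weighted-least-squares
    logistic association tests of SNP frequencies with population
    systems, multilocus-genotype construction with ambiguity-averaged
    p-distances, UPGMA clustering, atomic-number encoding and stepwise
    linear discriminant classification, composite linkage
    disequilibrium, coding-sequence descriptive statistics, and a
    synthetic-cohort simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    MASS,
    phangorn,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
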