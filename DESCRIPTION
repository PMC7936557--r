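Package: strpopgen
Title: Forensic and Population-Genetic Analysis of Autosomal STR Loci
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for short tandem repeat (STR) population
    studies: per-locus forensic efficiency parameters (observed and unbiased
    expected heterozygosity, polymorphism information content, matching
    probability, powers of discrimination and exclusion, and their combined
    forms), Monte-Carlo exact Hardy-Weinberg testing, genotypic linkage
    disequilibrium permutation tests with EM-based composite r-squared,
    Nei's DA genetic distances with allele-permutation differentiation
    tests, neighbor-joining tree construction, classical multidimensional
    scaling and principal component analysis of allele-frequency vectors,
    and a Balding-Nichols drift simulator for generating synthetic
    populations and genotype tables. Ships a transcription of a published
    22-locus allele-frequency table for a Han population (590 individuals)
    as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
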