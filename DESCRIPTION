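Package: genecol
Title: Genecological Analysis of Local Adaptation from Genomic, Climatic and Geographic Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for evaluating genomic, climatic and geographic data as
    descriptors of local adaptation in widespread plant populations sampled in
    common gardens. Provides structure-corrected genotype-phenotype association
    (mixed linear model with a genomic relationship matrix), genotype-environment
    association under an allele-frequency covariance model (closed-form Bayes
    factors and whitened rank correlations with consensus filtering across
    chains), cross-validated principal-component regression for comparing
    predictor sets, climate-driver ranking and congruence statistics, k-means
    clustering of allele-frequency clines with variance restoration, expected
    heterozygosity and proportional-polymorphism summaries, and a seeded
    synthetic-data generator that plants rangewide and localized allele-frequency
    clines with polygenic common-garden phenotypes for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
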