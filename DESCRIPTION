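Package: arabpop
Title: Population Structure, Admixture Statistics, Autozygosity and
    Imputation Evaluation for Cohort Genomics
Version: 1.0.0
Authors@R: person("arabpop", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An analysis pipeline for whole-genome cohort studies of admixed
    human populations: sample- and variant-level quality control (exact
    Hardy-Weinberg test, missingness and minor-allele-count filters),
    population structure (LD pruning, genotype PCA, allele sharing,
    dominant-ancestry assignment from admixture fractions), f3 and
    Patterson's D admixture statistics with weighted block-jackknife
    standard errors, Hudson and Weir-Cockerham FST, a two-state HMM caller
    for runs of homozygosity with Gaussian-mixture size classification and
    inbreeding coefficients, Y-chromosome sub-haplogroup discovery on
    bootstrapped trees with lineage dating, and imputation-accuracy
    evaluation by aggregate R-squared in allele-frequency bins.  A
    synthetic-cohort generator (Balding-Nichols drift, Dirichlet admixture,
    planted autozygous tracts, simulated haploid phylogenies, panel/target
    splits) provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
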