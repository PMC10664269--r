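Package: kinegen
Title: Kinematic Phenotyping and Genetic Association for Ballistic Jump Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sports-genomics studies that phenotype
    explosive lower-limb performance with optical motion capture and a force
    platform, and test candidate-gene associations (ACTN3 R577X, ACE I/D)
    against the derived outcomes. Provides readers for marker and force-plate
    TSV exports and genotype tables; zero-phase low-pass filtering and
    numerical differentiation of marker signals; joint-angle computation for
    hip and knee from marker triplets; force-based phase segmentation of squat,
    countermovement and drop jumps; per-trial outcomes (relative torque, power,
    rate of force development, reactive strength index, index of reactive
    force, jump heights, contact and sprint times); statistical-genetics
    routines (Hardy-Weinberg equilibrium, genetic-model coding, one-way ANOVA
    with Tukey HSD and eta-squared, genotype-group t-tests, likelihood-ratio
    covariate tests, Monte-Carlo power analysis); and a physics-based
    synthetic-trial and cohort generator with ground-truth labels so every
    stage is testable without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
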