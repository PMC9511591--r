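Package: famh2
Title: Two-Stage Heritability Analysis for Three-Generation Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the broad heritability of continuous
    phenotypes in maternal-line three-generation family cohorts
    (grandmother, mother, child). Stage 1 applies the random family method:
    covariate-adjusted regression of the offspring trait on the parental
    trait, with an empirical null distribution of the slope built by
    derangement-constrained re-pairing of families and an exact empirical
    p-value p = c/n. Stage 2 estimates variance components under a linear
    mixed model with a pedigree-derived genetic relatedness matrix, by
    restricted maximum likelihood, Gibbs sampling and Hamiltonian Monte
    Carlo, and reports heritability h2 = sigma_g2 / (sigma_g2 + sigma_e2).
    Includes pedigree kinship computation, cardiovascular phenotype
    derivation rules (Devereux left-ventricular mass, body-surface-area
    indexing, blood-pressure and BMI categories), a synthetic family-trait
    generator with known genetic architecture, and an end-to-end pipeline
    with reproducible reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
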