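Package: darscale
Title: Diversity-Area Relationship Scaling for Microbiome Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Diversity-area relationship (DAR) analysis for multi-site
    microbiome cohorts. Computes Hill-number diversity profiles, builds
    diversity-accrual curves over randomized sample accumulation orders,
    fits power-law (PL) and power-law-with-exponential-cutoff (PLEC)
    accrual models, and derives the scaling parameter z, the pairwise
    diversity overlap g, the maximal accrual diversity Dmax, and the
    ratio of individual to population diversity (RIP) across diversity
    orders q. Includes inter-individual (per body site) and intra-tract
    (across sites) resampling designs, permutation tests for pairwise
    parameter differences between sites, multi-level taxonomic
    collapsing, and a seeded synthetic-cohort generator with calibratable
    occupancy structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, biomformat, data.table,
    withr, ggplot2
Suggests: testthat (>= 3.0.0), vegan, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
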