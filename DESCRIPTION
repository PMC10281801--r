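Package: sociality
Title: Proximity-Based Social Phenotypes and Their Variance Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds yearly, sex-partitioned social phenotypes (social
    tendency, degree, mean half-weight association index, conspecific
    density in the 50% kernel core home range) from longitudinal
    georeferenced sighting records of individually identified animals, and
    partitions their variance with Bayesian multivariate generalized linear
    mixed models. Supports heterogeneous-variance (idh) and fixed-variance
    free-correlation (corgh) random-effect structures over individual and
    year, Gaussian and Poisson(log) responses with observation-level
    overdispersion, latent- and observed-scale repeatability, among-individual
    trait correlations, and correlations between repeatable social traits and
    a single-measure Poisson fitness trait. Includes a synthetic-data
    generator with known ground truth for sampler validation and end-to-end
    pipeline tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rjags,
    coda,
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
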