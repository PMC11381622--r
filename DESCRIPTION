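Package: phenomap
Title: Patient Phenotyping with Generative Topographic Mapping and
    Two-Level Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Derives clinical phenotypes from tabular cohort data by a
    two-level clustering strategy: a Generative Topographic Mapping (GTM)
    latent-variable model fitted by expectation-maximisation yields soft
    micro-clusters of subjects on a two-dimensional latent lattice, and
    Ward's minimum-variance agglomerative clustering of the GTM reference
    vectors merges the micro-clusters into macro-cluster phenotypes.
    Includes the supporting preprocessing chain (validity masking, unit
    harmonisation, missingness filtering, log transformation of skewed
    variables, multivariate iterative imputation, standardisation),
    cross-validated hyperparameter selection by held-out negative
    log-likelihood, latent-map interpretation layers (membership,
    reference, investigative and per-subject probability maps), post-hoc
    phenotype characterisation statistics, a seeded synthetic-cohort
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
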