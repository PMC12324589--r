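Package: plsmodes
Title: Supervised Latent-Mode Subtyping of a Binary Trait from Multimodal Brain Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A supervised pattern-learning pipeline for discovering and
    validating latent brain subtypes of a dichotomized trait such as
    chronotype. Fits single-response partial least squares (NIPALS PLS1)
    between a participants-by-features brain matrix with named modality
    blocks (grey-matter volume, white-matter fractional anisotropy,
    functional connectivity) and a -1/+1 trait, assesses latent-mode
    significance by permutation of the trait, quantifies loading stability
    by bootstrap resampling with Hungarian component matching and
    percentile confidence intervals, projects unseen cohorts into the
    trained latent space through a block-restricted rotation, and profiles
    mode scores phenome-wide (PheWAS/DiaWAS/MedWAS style Pearson scans
    with per-family Bonferroni correction), with sex-difference tests and
    age-bracket stratification. Includes cohort-preparation utilities
    (trait recoding, concordance and shift-work exclusion filters,
    confound residualization) and a synthetic-cohort generator with
    planted low-rank trait-linked modes that provides ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
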