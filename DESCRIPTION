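Package: subtypeforge
Title: Discovery, Validation and Copy-Number Characterization of Tumor
    Expression Subtypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for molecular subtype analysis of tumor
    cohorts: resampled consensus clustering of gene-expression profiles with
    CDF/delta-area model-selection diagnostics, Monte-Carlo cluster
    significance testing against a Gaussian null, silhouette-based core-sample
    selection, a balanced nearest-centroid subtype classifier with
    cross-study centroid validation and mean/SD harmonization of external
    cohorts, recurrent DNA copy-number aberration detection by cyclic-shift
    permutation with bootstrap peak localization and peel-and-repeat,
    gene-level gain/loss calling, a chromosomal instability index, SAM-style
    permutation differential expression, and the contingency-table,
    Kruskal-Wallis and log-rank association tests used to link subtypes to
    clinical covariates and outcomes. Includes seeded synthetic-cohort
    generators with known ground truth for end-to-end testing.
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
    survival,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
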