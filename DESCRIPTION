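Package: nutrimedmr
Title: Mediation and Mendelian Randomization Analysis of Macronutrient
    Intake and Cardiometabolic Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-arm causal analysis of macronutrient intake
    and cardiometabolic outcomes. One arm decomposes diet-outcome
    associations through adiposity and physical activity with pairwise,
    parallel and serial mediation path models, bootstrap inference,
    nested-model likelihood-ratio tests, collinearity screening and
    false-discovery-rate control. The other arm performs two-sample
    Mendelian randomization on GWAS summary statistics: instrument
    selection with LD clumping, allele harmonization, inverse-variance
    weighted, MR-Egger, weighted median, robust adjusted profile score
    and MR-PRESSO estimators, with heterogeneity, pleiotropy and
    leave-one-out diagnostics. Includes dietary-variable preprocessing
    (energy adjustment by the residual method, energy percent,
    added/total sugar derivation, Friedewald LDL, lipid-medication
    correction, nutrient-pattern principal components) and a
    synthetic-data generator with known ground truth for cohorts and
    GWAS summary pairs.
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
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
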