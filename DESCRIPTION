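Package: hpdkinetics
Title: Tumor Growth Dynamics, RECIST 1.1 Response, and Hyperprogression
    Classification for Immunotherapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for retrospective immuno-oncology biomarker analyses built
    on longitudinal target-lesion measurements: RECIST 1.1 response
    categories, best overall response and progression-free survival; tumor
    growth kinetics (TGK) and volume-calibrated tumor growth rate (TGR) with
    their pre/on-treatment fold changes; the two-criterion hyperprogressive
    disease (HPD) rule (time to treatment failure under 2 months plus either
    a 50% tumor-burden increase in first line or 2-fold TGK and TGR increases
    in second line); chromosome 11q13 amplification annotation from
    gene-level copy-number calls; cohort statistics (exact and chi-square
    contingency tests, Mann-Whitney, Kaplan-Meier, log-rank, Cox regression
    with interaction terms); and a seeded synthetic-cohort generator so the
    whole chain is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
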