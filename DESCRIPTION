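Package: scitmodel
Title: Population-Based Markov Cohort Model of Allergen Immunotherapy in
    Allergic Rhinitis and Asthma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic Markov cohort model of allergic rhinitis (AR) and
    allergic asthma (AA) progression in the German population aged 6 to 65
    years, 2011 to 2050, under subcutaneous allergen immunotherapy (SCIT)
    policy scenarios. Sub-cohorts stratified by age group, allergy type and
    treatment arm are propagated through six health states in yearly cycles;
    payer-perspective state costs and three-year SCIT drug costs are accrued,
    discounted, and compared across supply-rate scenarios via incremental
    cost-effectiveness ratios. Includes incidence calibration to a population
    projection, probabilistic sensitivity analysis with common random numbers,
    and a synthetic-data generator for the demographic and transition-
    probability inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
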