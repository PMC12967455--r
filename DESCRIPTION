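Package: phdiet
Title: Planetary Health Diet Adherence from Dietary Survey Microdata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses population adherence to the EAT-Lancet Planetary Health
    Diet (PHD) from individual-level dietary survey data. Disaggregates
    composite dishes into PHD food groups via standardised recipe proportions
    (with nutritional gating of encouraged ingredients in unhealthy
    preparations), standardises intakes to grams per 2500 kcal, excludes
    extreme energy reporters, computes post-stratification survey weights
    against national age-sex population margins, and scores food-group
    compliance plus three composite indices: the World Index for
    Sustainability and Health (WISH, 0-130), the EAT-Lancet Index (ELI, 0-42)
    and the unbounded EAT-Lancet Diet Index (ELD-I). Cohort analytics cover
    population-weighted pooled means, deviation-from-pooled-mean tests,
    DerSimonian-Laird heterogeneity (I2), general dominance analysis of
    food-group contributions to index variance, weighted demographic
    regressions with eta-squared effect sizes, and between-index concordance.
    A seeded multi-country synthetic survey generator reproduces the
    statistical structure of harmonised European dietary surveys so the whole
    pipeline is testable without access-restricted national microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
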