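Package: proxfert
Title: Bongaarts Proximate-Determinants Decomposition of Fertility from
    Survey Microdata
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the Bongaarts aggregate fertility model from
    individual-level women's survey records: age-specific fertility and
    marital-fertility schedules from birth histories with person-month
    exposure, the indices of marriage (Cm), contraception (Cc), postpartum
    insusceptibility (Ci) and abortion (Ca), their combination into a
    predicted total fertility rate (TFR = Cm*Cc*Ci*Ca*TF, TF = 15.3), and
    stratified decomposition by socioeconomic group. Ships a seeded monthly
    microsimulation generating survey cohorts with known true parameters so
    the whole pipeline is testable without restricted DHS microdata, plus a
    documented CSV schema, weighted descriptive tabulation and rendered
    decomposition tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
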