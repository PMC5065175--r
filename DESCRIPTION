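Package: icfsurvey
Title: Disability Measurement in Population-Based Cluster Surveys
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for measuring disability in all-age population-based
    surveys within the International Classification of Functioning,
    Disability and Health (ICF) framework. Scores clinical impairment
    screens (visual acuity, pure-tone audiometry, musculoskeletal
    assessment, seizure history, PHQ-9) and Washington Group self-reported
    functioning items into graded results; combines them into composite
    case definitions and the Category A/B/C decomposition of self-reported
    versus clinically screened cases; evaluates two-stage
    screening-cascade strategies; provides two-stage cluster-survey design
    helpers (sample size, probability-proportionate-to-size cluster
    selection, compact segment sampling) and cluster-robust prevalence
    estimation with design effects; and generates fully synthetic survey
    cohorts with a documented latent-severity and reporting model so that
    every analysis stage is testable without microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
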