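Package: mbcoud
Title: Measurement-Based Care Decision Support for Office-Based
    Buprenorphine Treatment of Opioid Use Disorder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic rules engine implementing measurement-based
    care for office-based buprenorphine treatment of opioid use disorder:
    scoring of the TAPS opioid screening gate, an 11-item DSM-derived OUD
    symptom checklist, and a two-item medication adherence questionnaire;
    a change-from-baseline treatment-response classifier (minimal/partial/
    full bands at 25% and 75% decrease combined with a past-2-week opioid
    use flag); and a longitudinal clinical decision support state machine
    over biweekly critical decision points in the first 12 weeks of
    treatment, with a 24 mg daily dose ceiling, adherence-alert precedence,
    continuation-phase transition after 4 weeks of sustained full response,
    and mandatory specialty referral for persistent non-response. Includes
    a seeded synthetic patient-trajectory generator, JSON trajectory I/O
    with validation, CSV export, and ggplot2 visualisations.
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
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
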