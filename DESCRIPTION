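Package: delphitriage
Title: Modified-Delphi Consensus and Traffic-Light Patient Prioritisation
    for Inpatient Pharmacy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for developing and running a consensus-based patient
    prioritisation tool for mental-health inpatient pharmacy teams. One half
    implements a modified-Delphi engine: Likert band summaries from long-format
    panel ratings, percent-agreement inclusion and risk-tier rules, round
    reports, controlled-feedback documents for second-round panellists, and
    first-choice rank aggregation with deterministic tie-breaks. The other half
    is the resulting triage engine: a machine-readable risk-indicator catalog
    with a small predicate grammar, red/amber/green classification of patient
    records with an amber-escalation rule and audited clinical-judgement
    overrides, and review scheduling on a working-day calendar. Seeded
    generators produce panel-rating matrices and patient cohorts with planted
    indicator matches so every component is testable without clinical data.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
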