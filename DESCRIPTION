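Package: hhcteams
Title: Team Sizing and Composition Models for Home Healthcare
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Decision-support models for dimensioning home-healthcare (HHC)
    teams. Weekly care demand is modelled as a discrete-time infinite-server
    queue with batch case arrivals, giving closed-form stationary and
    transient moments, a peakedness (variance-to-mean) summary that involves
    the Gini coefficient of the length-of-stay distribution, and a
    square-root staffing rule. Around this core the package provides
    case construction and Kaplan-Meier length-of-stay estimation from visit
    records, a square-root tour-length travel approximation, a binomial
    effective-capacity (absenteeism) model evaluated through the incomplete
    beta function, a hierarchical skill-mix optimizer with the normal
    expected-excess recursion, contract-mix bounds for avoiding split
    shifts, team-interaction complexity counts, a team-merging scenario
    engine with a weighted objective, and a seeded synthetic visit
    generator that doubles as a Monte-Carlo oracle for the demand model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
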