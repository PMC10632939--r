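Package: endgamesim
Title: Tobacco-Endgame Policy Simulation with a Discrete-Time Markov Cohort Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort model of adult cigarette-smoking
    prevalence under tobacco-control policy scenarios. The population evolves
    by age, sex and smoking state (never, current, former by quit duration)
    through stylized fertility, mortality, initiation, cessation and relapse
    schedules. A policy module converts MPOWER-style policy-level changes
    (smoke-free air laws, cessation support, health warnings, advertising
    bans) and real cigarette-price changes (via age-banded price elasticities)
    into multiplicative adjustments of prevalence, initiation and cessation.
    Scenario tooling covers a tobacco-free-generation sales ban and annual
    price escalation; a synthetic baseline is calibrated so the status-quo
    projection reproduces published Korean prevalence trajectories; one-way
    and probabilistic (beta-distributed, bias-corrected percentile bootstrap)
    sensitivity analyses assess robustness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
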