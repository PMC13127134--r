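Package: frailtydyn
Title: System Dynamics Projection of Frailty Prevalence, Service Use and
    Costs in an Ageing Population
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Deterministic stock-and-flow simulation of frailty dynamics in
    the population aged 50 and over, stratified into four age bands and four
    electronic Frailty Index (eFI) categories (fit, mild, moderate, severe).
    Projects annual frailty incidence, prevalence, primary and secondary or
    urgent care contacts and costs over a multi-year horizon; encodes policy
    scenarios as multiplicative interventions on transition or service rates
    and quantifies avoided service use and cost savings against baseline;
    recovers unpublished rate parameters by bounded least-squares calibration
    against target trajectories; and generates seeded synthetic parameter
    sets and truth trajectories so every stage is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
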