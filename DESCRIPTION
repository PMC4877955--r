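Package: saltsim
Title: Markov Cohort Modelling of Dietary Sodium Reduction Interventions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A closed-cohort Markov macro-simulation of dietary sodium
    reduction policies. An adult population stratified by sex, ethnicity and
    five-year age band moves annually through healthy, coronary heart disease,
    stroke and dead states under secular trends in incidence, case fatality
    and background mortality. Interventions reduce sodium intake, which lowers
    systolic blood pressure and scales cardiovascular incidence rates; the
    engine accrues discounted quality-adjusted life-years and health-system
    costs, compares each scenario against a do-nothing comparator (incremental
    QALYs, net costs, ICER or dominance), decomposes gains by demographic
    group, age at accrual and calendar decade, and propagates parameter
    uncertainty by Monte Carlo simulation. A synthetic-input generator
    emulates the administrative rate and cost surfaces the model consumes, so
    the full pipeline runs and is testable without access to restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
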