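Package: platformcost
Title: Economic Simulation of Platform Trials Versus Conventional Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Event-driven simulation of multi-arm survival trials with a
    shared control group, event-count-triggered interim futility analyses on
    failure-free survival and a final overall-survival analysis, together
    with a Monte-Carlo top-down costing model built from expert-elicited
    cost and time parameters (method-of-moments lognormal and normal
    distributions). Compares a single platform trial against conventional
    multigroup and two-group trial programmes evaluating the same set of
    interventions via matched-iteration relative differences in total cost,
    cumulative duration, and setup requirements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
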