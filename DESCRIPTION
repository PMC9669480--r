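Package: pfocea
Title: Cost-Effectiveness of Patent Foramen Ovale Closure After Cryptogenic Stroke
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quarterly four-state Markov cohort model comparing percutaneous
    patent foramen ovale (PFO) closure with medical therapy alone after
    cryptogenic stroke, parameterised for the Chinese healthcare setting.
    Implements the base-case cost-utility analysis (discounted costs, QALYs,
    life-years and ICERs), scenario analyses over antithrombotic regimens and
    alternative utility sets, a time-horizon sweep, one-way (tornado) and
    probabilistic sensitivity analyses with beta/gamma parameter
    distributions, cost-effectiveness acceptability curves, and an
    individual-level microsimulation used as a validation oracle for the
    cohort engine.
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
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
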