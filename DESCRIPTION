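Package: musclefrailty
Title: Frailty Phenotyping and Ex Vivo Muscle Contractility Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for percentile-based frailty phenotyping of mouse cohorts
    (deficit-accumulation frailty index, grip/rotarod/treadmill summaries,
    High/Low frailty-marker classification), extraction of contractile metrics
    from ex vivo muscle force-time traces (twitch kinetics, specific tetanic
    force, fatigue area under the curve, recovery kinetics), and the stratified
    factorial statistics used to compare them (unbalanced two-way ANOVA with
    Sidak post hoc tests, percent-change t-tests, repeated-measures three-way
    recovery analysis). A fully seeded synthetic-data generator emulates the
    cohort and trace structure so every stage of the pipeline can be exercised
    and validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
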