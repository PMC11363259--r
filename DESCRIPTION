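Package: opiflow
Title: Surgical Workflow and Objective Performance Indicator Analysis for
    Robot-Assisted Hysterectomy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the workflow of robot-assisted total
    laparoscopic hysterectomy (rTLH) from step annotations and robotic
    event streams. Cases annotated against a standardized step card are
    resolved into gap-aware timelines (a 2-second rule separates true
    inter-step gaps from immediate step changes), objective performance
    indicators (camera movement, energy activation and clutch event
    counts) are computed per surgical step, workflow signatures and
    START-augmented step-transition probability matrices are derived,
    and steps and surgeons are compared with two-sample t tests computed
    from raw values or from published summary statistics. A calibrated
    semi-Markov simulator generates synthetic annotated cases with
    per-step lognormal durations and Poisson event streams for method
    development and power exploration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
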