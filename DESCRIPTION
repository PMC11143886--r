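Package: cadprs
Title: System-Dynamics Modelling of Polygenic Risk Score Screening for
    Coronary Artery Disease Prevention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A stratified cohort (system-dynamics) simulator of acute
    coronary events in a national adult population, with a
    Framingham-based risk engine, polygenic risk score (PRS)
    stratification of event risk, statin intervention scenarios, and a
    health-economic evaluation layer (costs, QALYs gained, cost per
    QALY, net monetary benefit) with odds-ratio sensitivity brackets.
    Includes a synthetic-population generator standing in for national
    survey and registry calibration data, three built-in screening
    scenarios (maximal, intermediate, targeted), and a config-driven
    reproducible run pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
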