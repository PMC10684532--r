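Package: screenopt
Title: Optimization of Risk-Stratified Cancer Screening Intervals
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for choosing risk-group thresholds in risk-adapted cancer
    screening programmes. A deterministic natural-history model estimates the
    probability that a cancer is screen-detected rather than diagnosed in the
    interval between screens, and from it the expected advanced-cancer
    (node-positive) risk per risk stratum and screening regimen. Linear and
    integer programming then allocate screening intervals across risk
    quantiles to minimize expected advanced-cancer incidence under a
    constraint on the total number of screens. Includes quantile construction
    from case-control risk scores, threshold extraction on the risk-score
    scale, resource sweeps, sensitivity scenarios, a synthetic case-control
    score generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
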