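Package: floodhedge
Title: Individual-Based Simulation of Bet-Hedging Evolution Under Rare
    Extreme Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-time, individual-based simulation of the evolution of a
    continuous risk-avoidance trait (nest height of a riparian bird) under
    stochastic flooding, together with the analytical long-term mean-fitness
    theory that predicts when conservative bet-hedging phenotypes are favored.
    Long-term fitness is modeled as a geometric, arithmetic, or mixed mean over
    moderate- and extreme-condition fitness curves, with the balance set by the
    frequency and scope of extreme events and by the number of reproductive
    attempts per lifetime. Includes parameter-sweep and two-stage
    climate-change experiments that classify evolutionary outcomes
    (low-nesting, high-nesting, intermediate) and quantify extinction risk
    after abrupt increases in the frequency, scope, or intensity of extremes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
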