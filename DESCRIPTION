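Package: rescueCEA
Title: Cost-Effectiveness of Autonomous-Vehicle Deployment in Earthquake Rescue
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A three-state Markov cohort model (trapped, rescued, dead; 6-hour
    cycles) for the cost-effectiveness of mobilising government-controlled
    autonomous vehicles in post-earthquake rescue. Computes discounted
    quality-adjusted life years, itemised per-person costs, incremental
    cost-effectiveness ratios with dominance handling, one-way (tornado)
    sensitivity analyses, and seeded Monte Carlo probabilistic sensitivity
    analysis with triangular and Gamma input distributions, a
    cost-effectiveness plane and acceptability at willingness-to-pay
    thresholds. Includes a scenario generator for rescue/survival schedules at
    arbitrary efficiency improvements and a calibration search over the
    model's structural switches.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
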