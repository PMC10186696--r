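Package: dielshift
Title: Diel Activity Shifts and Predator-Prey Temporal Overlap
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify shifts in the daily activity of ectotherms
    under predation pressure. Estimates circular (time-of-day) activity
    densities by von Mises kernel smoothing or nonnegative
    trigonometric-sum maximum likelihood, builds a thermally "potential"
    activity distribution from preferred body temperatures (Pearson-system
    moment matching) and operative temperature logger series, and compares
    activity patterns with the coefficient of overlapping (Delta) using a
    smoothed bootstrap for percentile confidence intervals and rank-sum
    tests on bootstrap replicates. Includes a seeded synthetic-data
    generator emulating a bimodally active prey, a midday-active predator
    guild, gradient-selected body temperatures and multi-microhabitat
    operative temperature loggers, plus descriptive summaries of
    predation-related injury surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
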