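Package: sagame
Title: Simulation and Analysis of a Video-Based Situation-Awareness Game
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools to simulate and analyse a SAGAT-style hazard-perception
    video game for cyclists. Generates synthetic stimulus banks (masked video
    clips with overt, covert and empty probe locations), simulates
    equal-variance signal-detection observers with phase-wise learning,
    lognormal response times, gaze traces and counting-span working-memory
    transcripts, scores play with the game's points system, and computes the
    study's performance measures: log-linear corrected hit and false-alarm
    rates, sensitivity d', observed and prevalence-adjusted optimal decision
    criteria, response bias, partial-credit-unit working-memory scores, and
    dynamic area-of-interest glance statistics. Includes the inferential
    toolkit used to analyse such experiments: Welch's t-test with Cohen's d,
    mixed repeated-measures ANOVA with Greenhouse-Geisser correction and
    partial eta-squared, polynomial contrasts, linear regression with
    adjusted R-squared and nested-model F-tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    car,
    knitr
Config/testthat/edition: 3
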