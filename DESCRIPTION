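Package: camobreak
Title: Simulation and Analysis of Camouflage Visual-Search Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Procedural generation of bi-coloured striped search displays
    with illusory foreground squares and boundary-conditioned cryptic
    targets, randomised within-subject factorial session plans, a
    synthetic observer producing right-censored, 10 ms-rounded response
    times and wrong-side errors, maximum-likelihood estimation of
    censored log-normal response-time means, and a random-intercept
    mixed-model analysis chain (deviance chi-square tests, simple
    contrasts against a reference treatment, Tukey-type single-step
    pairwise comparisons, treatment-ordering summaries, and a classical
    repeated-measures ANOVA cross-check).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    multcomp,
    jsonlite,
    png,
    stats,
    graphics,
    utils
Suggests:
    survival,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
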