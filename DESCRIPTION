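Package: flockescape
Title: Sequence and Rate Analysis of Collective Escape in Bird Flocks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing collective escape behaviour of bird flocks
    chased by an artificial aerial predator (a robotic falcon or a drone).
    Provides an ethogram data model for timed chase event logs, descriptive
    summaries of escape frequency and composition, behavioural
    transition-sequence analysis under a fixed follow window with a
    fixed-margin permutation null (Patefield sampling of contingency tables),
    Poisson mixed-effects models of per-chase escape counts with Type-II Wald
    tests, estimated marginal means and Tukey pairwise contrasts, an
    altitude-binned escape-rate model, a pooled two-sample comparison of
    robotic and wild-falcon chases, and a synthetic event-stream generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    lme4,
    car,
    emmeans,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
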