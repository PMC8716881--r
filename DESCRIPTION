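Package: landsyn
Title: Muscle Synergy Analysis of Perturbed Single-Leg Landings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing the modular organisation of leg-muscle
    activity during single-leg drop landings on stable and unstable
    ground. Provides surface-EMG conditioning (zero-phase Butterworth
    filtering, rectification, linear-envelope extraction, amplitude
    normalisation), ground-reaction-force based landing segmentation and
    time normalisation onto a fixed 300-point cycle, muscle-synergy
    extraction via non-negative matrix factorisation with automatic
    model-order selection, unsupervised k-means classification of motor
    primitives and motor modules into fundamental and combined synergies,
    and spatiotemporal synergy metrics (full width at half maximum,
    circular centre of activity, primitive overlaps, joint coactivation
    index, centre-of-pressure confidence-ellipse area, and joint-moment
    rate scalars). A seeded synthetic-trial generator with known
    ground-truth synergy structure makes every stage testable end to end
    without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
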