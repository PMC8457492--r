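Package: audspeed
Title: Discrimination-Contour Analysis of Auditory Speed Perception
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-alternative forced-choice (2AFC) auditory speed
    discrimination experiments built on a distance-duration Weber-fraction
    stimulus plane: constant-stimuli trial-schedule generation, simulation of
    cue-weighted noisy observers, cumulative-Gaussian psychometric fitting with
    signed just-noticeable differences (JNDs) and a goodness-of-fit gate,
    discrimination-contour ellipse fitting (direct least-squares and algebraic
    conic variants), a signed radial speed statistic with inverted-curve JND
    conversion, and permutation statistics (sign-flip and label-shuffle t tests
    with exact enumeration, a permutation mixed ANOVA, corner chi-square
    comparisons and standard effect sizes) for comparing groups of observers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
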