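Package: fixpupil
Title: Event-Locked Analysis of Fixational Saccades and Pupil Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how fixational (micro)saccade rate and pupil
    size are modulated around self-paced motor actions in binocular 1000-Hz
    eye-tracking recordings. Implements a binocular velocity-threshold
    saccade detector, blink detection and interpolation for pupillometry,
    event-locked saccade-rate estimation with mutual overlap exclusion,
    finite-impulse-response deconvolution of pupil change-rate responses by
    ridge regression with leave-one-out penalty selection, cluster-mass
    sign-flip Monte Carlo statistics, per-event covariation regression, and
    extremum-latency measures including the pupil light reflex. A synthetic
    session generator with full ground truth supports parameter-recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
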