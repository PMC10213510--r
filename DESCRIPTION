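Package: rhythmshift
Title: Temporal-Shift Detection Experiments with Rhythm-Altered Speech
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis pipeline for a temporal-shift detection
    paradigm in which listeners judge whether the final word of a spoken
    sentence resumes at the correct time after a silent gap. Provides
    frame-wise sinusoidal time warping of the early sentence region with
    exact duration conservation, three-interval trial assembly with jittered
    inter-stimulus intervals, interleaved 2-down/1-up adaptive staircases
    with reversal-based threshold estimation, a parametric dynamic-attending
    observer model for simulating young and older listener cohorts, and the
    downstream statistics: difference scores, paired t tests with Cohen's d,
    Pearson correlations with battery covariates, and split-plot ANOVA with
    Greenhouse-Geisser correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    withr,
    ggplot2
Config/testthat/edition: 3
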