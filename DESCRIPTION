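Package: crowdeda
Title: Electrodermal Activity Pipelines for Crowd Walking Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing ambulatory skin-conductance (electrodermal
    activity, EDA) recordings from pedestrian-dynamics experiments in which
    walking speed is either imposed externally or constrained by crowd
    density on a closed single-file course. Provides reading and segmenting
    of 32 Hz conductance traces, zero-phase Butterworth filtering,
    rule-based artifact screening with accelerometer coincidence, a
    convex-optimisation decomposition of conductance into tonic level and
    sparse-driver phasic responses, per-condition features (mean skin
    conductance level, non-specific response counts and amplitudes, and
    sympathetic band power in 0.045-0.25 Hz), single-file oval design
    quantities with proxemic zone classification, a repeated-measures
    statistical harness (Lilliefors screening, Friedman and
    Greenhouse-Geisser corrected ANOVA, Bonferroni post hocs, mixed models),
    and a seeded synthetic-cohort generator with ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    splines,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    nortest,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
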