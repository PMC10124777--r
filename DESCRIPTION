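Package: gazeomi
Title: Eye-Tracking Biomarkers of Social Attention: Gaze-to-Face Composite
    and Pupillary Light Reflex
Version: 0.1.0
Authors@R: person("ABC", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing and psychometric evaluation of eye-tracking
    biomarkers for school-age autism research. Maps raw gaze samples to
    stimulus regions of interest, applies trial/session/timepoint quality
    control gating, aggregates percentage-of-looking variables into an
    equal-weight Oculomotor Index of gaze to human faces (OMI), estimates
    pupillary light reflex latency and relative constriction, and runs the
    evaluation battery: acquisition reporting, construct validity against
    area-based chance levels, six-week stability via two-way intraclass
    correlations, heteroskedasticity-robust (HC3) group discrimination,
    and Spearman clinical correlations with optional rank-based partialing.
    A calibrated synthetic-cohort simulator stands in for raw study data so
    that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
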