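Package: idcgaze
Title: Eye-Tracking Markers of Perceptual Decoupling During Internally
    Directed Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for binocular eye-tracking studies of
    internally directed cognition (e.g. mental arithmetic with visual
    distractors): blink detection and padding, physiological-range and
    per-participant outlier exclusion, velocity-threshold saccade and
    microsaccade detection with binocular merging, extraction of six eye
    parameters (blink, saccade and microsaccade rate, fixation disparity,
    pupil diameter, gaze at center) in 500 ms bins with trial-wise
    subtractive baseline correction, and an inferential layer with paired
    t tests, Cohen's d_z, Bonferroni correction, JZS default Bayes factors,
    two-factor repeated-measures ANOVA and noncentral-t power analysis.
    Includes a seeded synthetic-recording generator with ground-truth event
    logs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
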