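Package: noisegaze
Title: Oculomotor Analysis of Prolonged-Fixation and Memory-Guided-Saccade
    Tasks Under White-Noise Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for binocular eye-tracking studies of oculomotor
    inhibitory control: reads 600 Hz gaze sample streams in normalized screen
    coordinates, converts them to degrees of visual angle, detects fixations
    with a windowed two-means clustering detector and derives saccades as
    displacements between consecutive fixations. Implements data-quality
    screening (sample-to-sample RMS precision, accuracy offset, data loss,
    both-eye exclusion rules), the prolonged-fixation measures (fixation ratio,
    intrusive saccades), the memory-guided-saccade measures (anticipatory
    saccades, latency, gain, five-criterion correct-trial classification),
    variable transformations with mixed-model group-by-condition reports, and
    white-noise stimulus generation (uniform auditory noise WAV files, visual
    pixel-noise frame blending). A synthetic gaze generator plants recoverable
    group-by-condition parameters so every stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    lme4,
    lmerTest,
    emmeans
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
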