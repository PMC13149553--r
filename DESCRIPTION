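Package: speedenc
Title: Quantitative Analysis of Neuronal Speed Encoding in Locomotor Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how neuronal firing rate encodes locomotion
    speed in head-fixed rodent recordings. Implements peri-event alignment of
    spike trains to running onsets and sensory stimuli, classification of
    running-related (R-) neurons by paired rank tests, cross-correlation lag
    estimation between firing rate and running speed with a circular-shift
    permutation null, fitting of the saturating single-phase association model
    v = v_m (1 - exp(-(f - f0)/tau)) with population normalization, and
    analysis of optogenetic frequency dose-response curves. Includes a
    synthetic-session generator with ground-truth labels for validating every
    stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
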