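Package: stresskit
Title: Quantification of Arousal- and Stress-Related Neurophysiology and
    Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying hyperarousal- and stress-related readouts
    in rodent experiments: fiber-photometry calcium-transient analysis with
    isosbestic correction and randomized-baseline thresholding, trajectory
    based behavioral event detection in standard arenas (elevated plus maze,
    open field, chamber assays), acoustic-startle and prepulse-inhibition
    quantification from high-speed pose keypoints, pupillometry timecourses,
    and slice-electrophysiology feature extraction (F-I curves, rheobase,
    action-potential threshold and half-width, passive membrane properties,
    miniature postsynaptic currents, synaptic connectivity classification,
    and long-term potentiation normalization).  Every input modality has a
    matching synthetic-data generator with known ground truth, so the whole
    pipeline is testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
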