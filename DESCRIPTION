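Package: optovis
Title: Analysis of Optogenetic Perturbations of Visual Thalamocortical Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing extracellular recordings from mouse visual
    cortex and thalamus under optogenetic perturbation of thalamic reticular
    neurons. Provides a session data model with trial assembly and
    locomotion-state segmentation, a synthetic-session generator with known
    ground truth, LFP wavelet power spectra with 1/f correction and band
    summaries, current source density, waveform-based narrow/broad-spiking
    classification, firing-rate statistics, plug-in mutual information between
    spike counts and stimulus classes, diagonal-covariance linear discriminant
    population decoding with leave-one-out cross-validation and
    spike-count-matched comparisons, and hierarchical (subject-stratified)
    permutation tests for nested group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    signal,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
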