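Package: cofire
Title: Detection and Longitudinal Tracking of Neuronal Co-Activation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chronic multi-area extracellular recordings:
    detection of neuronal ensembles (cell assemblies) from binned, z-scored
    spike trains via the Marcenko-Pastur eigenvalue bound, independent-component
    pattern extraction and Otsu membership thresholding; quadratic ensemble
    activation-strength traces; sharp-wave ripple (SWR) detection from laminar
    LFP by the normalized-squared-signal method with template-based event
    alignment; ensemble lifetime and SWR-tuning classification across sessions;
    and spike-sorting quality plus cross-session single-unit tracking metrics
    (SNR, ISI violations, nearest-neighbor Mahalanobis distance, waveform
    correlation, standardized mean difference). Includes a seeded synthetic-data
    generator with planted ensembles, ripples and drifting waveforms so the
    whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
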