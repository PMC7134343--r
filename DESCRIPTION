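Package: duallayer
Title: Dual-Layer EEG Artifact Removal and Gait-Cycle Time-Frequency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Signal-processing toolkit for mobile electroencephalography (EEG)
    recorded with dual-layer electrode arrays, in which each scalp electrode is
    paired with a mechanically coupled but electrically isolated noise-only
    electrode. Implements frequency-domain noise cancellation of motion and
    electrical artifacts against the noise layer, windowed PCA and CCA subspace
    cleaning with noise-referenced criteria, a simplified artifact subspace
    reconstruction (ASR) comparator, stacked-channel ICA with spectral
    component-rejection rules, and gait-cycle time-warped event-related
    spectral perturbation (ERSP) analysis with bootstrap significance masking
    and permutation statistics across walking speeds. Includes a synthetic
    dual-layer walking-EEG generator with known ground truth, and readers and
    writers for BDF/EDF recordings, gait-event tables, and electrode montages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    tools,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
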