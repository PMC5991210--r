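Package: ildtuning
Title: Interaural Level Difference Tuning Analysis for Two-Photon Calcium Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete analysis pipeline for two-photon calcium imaging
    studies of binaural sound processing in auditory cortex: baseline-corrected
    and neuropil-corrected delta-F/F0 extraction, per-trial peak responses,
    statistical identification of sound-responsive and ILD- or
    frequency-sensitive neurons, ILD tuning-curve summaries (peak, slopes,
    weighted centroid), frequency response areas and best frequency,
    binaural interaction classification (EO/OE/EE/OO-F with the binaural
    interaction index), principal components analysis of population ILD
    responses, an opponent-channel single-trial ILD decoder with
    leave-one-out cross-validation, pairwise signal and noise correlations
    with bootstrap shuffle nulls, bootstrapped spatial-clustering tests of
    tuning maps, and tonotopic-gradient estimation. Includes a synthetic
    experiment generator (GCaMP-like transients, neuropil contamination,
    planted tuning, binaural classes, tonotopic gradients and spatial
    clusters) that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    car,
    data.table,
    jsonlite,
    rlang,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
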