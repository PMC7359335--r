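Package: retinachrome
Title: Chromatic-Processing Analysis of Two-Photon Retina Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for chromatic (UV vs. green) processing in
    two-photon functional recordings of the mouse retina, from scan-field
    movies to per-cell spectral-contrast and color-opponency statistics and
    group-level permutation tests. Includes correlation-based ROI
    segmentation with layer-specific size constraints, delta-F/F trace
    extraction and preprocessing, event-triggered stimulus kernel and
    stimulus-triggered event kernel estimation, response quality indices,
    spectral contrast for same-polarity and antagonistic center/surround
    responses, full-field opponency, density recovery profiles, field
    entropy, direction selectivity, functional group assignment via a match
    index, and a stratified permutation test for group-level opponency
    enrichment. A synthetic-data module generates ground-truth cone, bipolar
    and ganglion-cell-layer recordings so every stage is testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    withr,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
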