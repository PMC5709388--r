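Package: OrganoidScreen
Title: Per-Organoid Live/Dead Image Analysis for 3D Tumor Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies treatment response in architecturally complex 3D tumor
    cultures from per-well image triplets (brightfield, calcein-AM live
    fluorescence, propidium-iodide dead fluorescence). Organoids are segmented
    from brightfield by adaptive local-mean thresholding, size-filtered,
    cleared of out-of-focus objects via Otsu binarization of the summed
    fluorescence, and indexed; fluorescence background is estimated from
    no-treatment controls by the dilated-inverse-mask median; per-organoid
    readouts (total area, intensity-ratio viability, thresholded live and dead
    areas) feed group summaries, dose-response fits, regressions, and viability
    heatmaps. A seeded synthetic-scene generator with per-pixel ground truth
    makes every stage testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
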