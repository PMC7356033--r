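Package: granulovol
Title: Platelet Dense-Granule Morphometry and Storage-Pool Volume Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Morphometric analysis of platelet dense granules from whole-mount
    transmission electron microscopy style images. Detects and measures
    electron-dense granules, computes per-platelet and per-patient storage-pool
    statistics (granules per platelet, equivalent diameter, mean and total
    dense-granule volume), builds control reference ranges and classifies
    subjects into storage-pool deficiency categories, types uranaffin-reacted
    granule cross-sections into developmental stages, resolves superimposed
    spherical granules from tilt series, and quantifies platelet adenine
    nucleotides from luciferase luminescence via a standard curve. Includes a
    seeded synthetic-data generator that renders whole-mount images, thin
    sections, and tilt-series stacks with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
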