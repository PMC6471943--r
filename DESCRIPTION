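Package: kidneyscreen
Title: Smart-Microscopy Screening and Quantification of Zebrafish Pronephric Cysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end high-content screening workflow for GFP-labelled
    zebrafish pronephroi in 96-well plates: simulated feedback ("smart")
    microscopy that detects and centres the pronephros in low-magnification
    pre-scans and emits high-resolution re-acquisition jobs; z-stack
    preprocessing (focus detection, sub-stack extraction, maximum projection,
    denoising, centred cropping); image quality control (blur and blank
    detection by intensity and Laplacian variance); heuristic wild-type versus
    cystic phenotype classification (zero-run intensity profiles confirmed by
    best-fit ellipse major axes); and morphometric cyst-area quantification
    (convex hull, Feret-diameter particle filtering) with plate heatmaps.
    Ships a ground-truthed synthetic plate generator so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
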