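Package: wsicascade
Title: Fast Cascaded Tumor-Region Segmentation for Whole-Slide Pathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fast, refined tumor-region segmentation of
    whole-slide pathology images (WSIs) using a two-stage cascade: Otsu
    tissue preselection on the HSV saturation channel at 1.25x
    magnification, a rough classifier heatmap at 1/128 of the slide side,
    and a dense segmentation heatmap at 1/8 of the slide side assembled by
    overlap-averaged stitching of large test tiles. Includes Camelyon-style
    evaluation (slide-level AUC, lesion-level FROC, mIoU and Tumor-mIoU
    with bootstrap confidence intervals), export of tumor-region polygons
    as ASAP-compatible XML for computer-aided annotation, a pluggable
    model contract with oracle test models, and a seeded synthetic
    pyramidal-slide generator so the full pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    igraph,
    png,
    stats,
    tiff,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
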