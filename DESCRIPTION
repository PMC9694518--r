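Package: fasgaseg
Title: Automatic Tissue Segmentation of FASGA-Stained Grass Internode
    Cross Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Parameter-free segmentation of brightfield images of
    FASGA-stained grass (maize, sorghum, miscanthus) internode cross
    sections into 40 histological tissue types. Pixels are classified by
    fixed saturation and value ranges in HSV space; spatial region masks
    (dark rind, vascular bundles, light rind, medullary pith) are derived
    automatically from the density of low-saturation pixels; pixel class
    and region membership are combined into a named tissue taxonomy, with
    a hue-based refinement of the lignified and poorly lignified
    medullary parenchyma. Per-tissue areas are quantified as pixel
    counts, physical areas and percentages of their region, and grouped
    region summaries are produced. A synthetic phantom generator renders
    cross-section images with known ground truth for validation, and a
    batch driver processes whole directories of images with identical
    settings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jpeg,
    tools,
    jsonlite,
    tibble,
    ggplot2,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
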