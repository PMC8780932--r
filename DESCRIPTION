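Package: stainpal
Title: Trainable Color-Palette Classification and Quantification of
    Stained Histology Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Learns a positive-color palette from polygon-annotated
    training regions of brightfield histology images (H&E, Sirius red,
    MSB, chromogenic TUNEL), batch-classifies RGB images pixel by pixel
    against the trained palette, cleans the resulting masks with
    background exclusion, morphological operations and connected-component
    size filters, and quantifies percent positive area and class-area
    ratios per image field. Includes an axis-aligned RGB box-threshold
    baseline classifier, segmentation-agreement metrics (sensitivity,
    specificity, accuracy, precision, Youden's J, F-score, Matthews
    correlation coefficient) against consensus hand-traced reference
    masks, a deterministic synthetic-image generator with pixel-exact
    ground truth for validation, and a command-line pipeline for
    train/run/evaluate/simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
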