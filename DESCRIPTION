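Package: bitewing
Title: Bitewing Radiograph Segmentation and Interdental Edge Enhancement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for classical image processing of dental bitewing
    radiographs: projection-profile single-tooth segmentation (mean filtering,
    global binarization, jaw splitting, interdental valley detection),
    an interdental edge-enhancement pipeline (median and bilateral filtering,
    adaptive binarization, binary morphology, Canny edge detection with a
    colored overlay), dataset balancing and two-stage train/test/validation
    splitting, and object-detection evaluation metrics (precision, recall,
    specificity, IoU-matched mean average precision). Includes a seeded
    synthetic bitewing phantom generator with exhaustive ground truth for
    validating every stage, and a command-line interface covering the full
    phantom -> segment -> enhance -> split -> evaluate chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
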