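Package: darcspot
Title: Automated Labeling and Counting of Apoptosing Retinal Cells in
    Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and counts fluorescently labeled apoptosing retinal
    cells (DARC, Detection of Apoptosing Retinal Cells) in confocal
    scanning laser ophthalmoscope images. Implements a two-stage pipeline:
    local luminance/contrast gain control (a Gaussian-weighted local
    z-score) followed by Laplacian-of-Gaussian band-pass filtering, then
    global thresholding at a multiple of the image standard deviation,
    connected-component extraction, moment-based blob morphometry, and
    rule-based classification of blobs into cells, vessels and noise.
    Includes a seeded synthetic image generator with ground truth for
    validation, detection scoring (precision/recall), overlay rendering,
    batch CSV output, and method-comparison statistics (Pearson
    correlation, intraclass correlation with confidence intervals,
    Cronbach's alpha, paired t-tests and percent-difference Bland-Altman
    limits of agreement) for comparing automated counts with manual
    raters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    jpeg,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
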