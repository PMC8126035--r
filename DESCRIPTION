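Package: hemocount
Title: Marker-Free Detection and Counting of Granular Hemocytes in
    Brightfield Histology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-assisted identification and counting of granular
    hemocytes in hematoxylin-eosin stained brightfield micrographs without
    immunohistochemical markers. Bright non-tissue background is removed by
    green/blue channel thresholds; each pixel is represented by the colour
    intensities of its spatial neighbourhood (multivariate image analysis),
    projected onto a principal component model trained on a hemocyte-only
    mosaic, and segmented by a score threshold. Connected objects are
    filtered by shape (area, width, height, circularity, solidity) and
    counted, and counts are compared across experimental groups with one-way
    ANOVA and the Tukey-Kramer test. A synthetic micrograph generator with
    ground truth supports calibration and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
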