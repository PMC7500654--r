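Package: ringverdict
Title: Quantifying the Distinctness of Softwood Growth-Ring Boundaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computer-aided detection of distinct growth-ring boundaries in
    softwood cross-section micro-images. A slide is cropped into vertical
    strips, each strip is binarized with an automatic mean-plus-standard-
    deviation gray threshold, slope-corrected row black-pixel profiles are
    built, and an abrupt earlywood-to-latewood transition band is searched
    for in each strip. Strips are aggregated by majority vote into a
    slide-level verdict with a quantitative "distinct degree" percentage and
    the corresponding IAWA softwood feature code (40p/41p). Includes a
    parameterized synthetic ring-image generator with ground-truth labels
    for end-to-end validation, profile plotting, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    tiff
Suggests:
    jpeg,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
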