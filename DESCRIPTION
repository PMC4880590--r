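Package: leafspad
Title: Optimal Leaf Positions for Chlorophyll-Meter Measurements from Leaf Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to locate the most representative position for SPAD
    chlorophyll-meter readings on a cereal leaf blade. Maps chlorophyll
    distribution along the blade from flatbed-scanner images via a linear
    red-band digital-number calibration, fits a quadratic chlorophyll
    profile, computes the leaf-area-weighted representative SPAD value by
    numerical integration over the irregular blade shape, inverts the
    profile to candidate measurement positions, and selects among them by
    measurement variance. Includes a synthetic leaf-scan generator so the
    full pipeline is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
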