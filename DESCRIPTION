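Package: wheatfrost
Title: Monitoring Spring Frost Damage to Winter Wheat from NDVI Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for mapping and assessing spring frost damage to winter
    wheat from dense red/near-infrared reflectance time series. Implements
    per-pixel NDVI computation and Savitzky-Golay smoothing, reference-curve
    construction by shape-model fitting of a multi-year average phenology
    curve, a cumulative Spring Frost Damage Index (SFDI) over the frost
    window, a self-adapting statistics correction (SASC) that matches the
    mapped affected area to an official statistic, and validation helpers
    (accuracy rate, yield-reduction rates, severity classes, regression
    diagnostics). A synthetic-scene generator with known frost truth supports
    end-to-end testing without satellite downloads.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    geosphere,
    signal,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
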