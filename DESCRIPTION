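Package: precipval
Title: Validating Gridded Precipitation Products Against Tree-Ring and
    Vegetation Greenness Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to compare competing gridded monthly precipitation
    products by how much inter-annual variance they explain in biological
    growth records.  Builds standardized tree-ring chronologies
    (supersmoother detrending, Tukey biweight averaging, autoregressive
    pre-whitening), assembles 8-month lagged regression designs under
    northern- and southern-hemisphere growing-season conventions, scores
    each site-by-product design with un-adjusted R-squared over the full
    period and in 21-year moving windows, and elects a best product per
    region with Condorcet ranked-ballot tallying.  Includes a synthetic
    study generator with planted noise structure for parameter-recovery
    testing, and readers/writers for Tucson decadal RWL ring-width files
    and the project's tabular formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
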