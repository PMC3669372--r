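Package: paestate
Title: Protected-Area Effectiveness from Land-Conversion Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well a protected-area estate has
    resisted habitat conversion, using a compare-to-everywhere design.
    Builds time-resolved protected-area layers from a site register,
    overlays them on gridded land-conversion fractions with exact
    area-weighted (fractional cell coverage) zonal statistics, and computes
    effectiveness statistics: inside/outside converted percentages, decadal
    conversion trajectories, standardised major axis (model II) regression
    with confidence intervals and a common-slope test, paired pre/post
    gazettement conversion rates, and size-conversion scaling. Includes a
    stochastic spatial land-conversion simulator with known ground truth so
    the whole pipeline is testable end to end on synthetic landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
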