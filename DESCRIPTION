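Package: cyclepm
Title: Mobile Low-Cost PM2.5 Exposure Analysis for Bicycle Sensor Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing opportunistic mobile air-quality campaigns in
    which low-cost PM2.5 sensor kits mounted on bicycles report 10-second
    measurements with GPS positions. Provides quality control of raw sensor
    streams (speed-window filtering, device-level screening against reference
    stations, trip trimming), hourly ratio calibration against official
    monitoring stations with guard rails and Leave-Station-Out validation,
    estimation of per-trip traffic-related PM2.5 increments by percentile
    background subtraction, aggregation of point increments onto metric grids
    with small-count suppression and quantile classification, and a fully
    synthetic campaign generator with a ground-truth ledger so every stage of
    the pipeline can be validated without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
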