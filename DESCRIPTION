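Package: streamtemp
Title: Timescale-Dependent Air-Water Temperature Models for Stream Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing how environmental controls on stream water
    temperature depend on the timescale of observation. Fits linear
    mixed-effects air-water temperature models with per-site random
    intercepts and air-temperature slopes and a continuous-time AR(1)
    residual correlation that tolerates gaps in the series; computes
    marginal and conditional (Nakagawa-Schielzeth) R-squared, adjusted
    intraclass correlation, population-level RMSE and variance inflation
    factors; and ranks environmental predictors by all-subsets dominance
    analysis (complete, conditional and general dominance plus Shapley-type
    relative importance) over an air-temperature-plus-catchment baseline.
    Includes a synthetic-data generator emulating a multi-catchment paired
    air-water logger network (hourly records, completeness-thresholded
    daily/monthly aggregation, burst missingness) so the whole pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    car,
    nlme,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
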