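Package: maxexposure
Title: Deterministic Modelling of Short-Term Maximum Individual Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for estimating the expected short-term maximum individual
    exposure downwind of an airborne hazardous release from high-frequency
    concentration time series. Extracts per-sensor statistics (mean, variance,
    fluctuation intensity, intermittency factor, autocorrelation integral time
    scale, peak windowed concentration), predicts maximum exposure with a
    deterministic peak-to-mean model, inverts the model for its proportionality
    constant and power-law exponent over sensor populations, quantifies their
    across-sensor variability with maximum-likelihood Gamma fits, and validates
    predictions with factor-of-two and factor-of-five metrics. Includes a
    seeded synthetic-data generator producing stationary concentration records
    with controllable moments, intermittency and integral time scale, and a
    batch pipeline orchestrating the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    data.table,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
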