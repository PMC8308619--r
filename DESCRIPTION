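Package: ncspath
Title: County-Level Natural Climate Solutions Emissions-Reduction Scenarios
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the potential of natural climate solutions (NCS)
    pathways - extended timber harvest rotations, cropland agricultural
    practices, avoided land conversion, and ecosystem restoration - to reduce
    county-level greenhouse-gas emissions over a 31-year horizon. Baseline
    activity rates and their historical variation drive three rule-based
    implementation scenarios (Limited, Moderate, Ambitious); enrolled activity
    is converted to annual CO2e fluxes via per-unit sequestration and
    avoided-emission rates, and rate uncertainty is propagated by Monte Carlo
    simulation with per-county, per-pathway quantile summaries. Includes a
    schema-validated CSV interface, a synthetic input-bundle generator with
    closed-form oracles, and reporting helpers for percent-of-goal and
    pathway-share arithmetic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
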