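Package: reefskill
Title: Skill Assessment of Modeled Subsurface Temperatures for Coral Reef
    Heat Stress Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating gridded ocean-model subsurface temperature
    output against in situ reef temperature logger records. Pairs
    high-frequency logger series with 3-hourly model snapshots, computes
    agreement statistics (Pearson correlation, bias, mean absolute error,
    RMSE), errors-in-variables (Deming) regression with a
    coefficient-of-variation based error-variance ratio, Taylor-diagram
    statistics overall and by spatial or temporal grouping, a generalized
    additive model of model bias over depth, distance to shore, day of year,
    year and location, coral heat-stress metrics (monthly climatological
    anomalies, seasonally detrended daily temperatures, 14-day means and
    coefficients of variation), and variance-scaled power spectral density
    with Daniell-kernel smoothing. Includes a synthetic paired-series
    generator with tidal and seasonal harmonics and injectable model errors
    for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    mgcv,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
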