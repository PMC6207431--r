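Package: mortseason
Title: Seasonality of All-Cause and Cause-Specific Mortality Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the seasonality of monthly death-rate
    time series stratified by age group, sex, cause of death and climate
    region. Builds month-length-corrected monthly death rates from stratified
    counts and July-anchored interpolated populations; detects 12-month
    periodicity with a Morlet continuous wavelet transform and a simulated
    white-noise null; locates the timing of maximum and minimum mortality with
    weighted circular means (centre of gravity and negative centre of gravity)
    and block-bootstrap confidence intervals; and estimates trends in the
    yearly peak-versus-trough percent mortality difference by
    inverse-variance-weighted least squares with Poisson delta-method
    standard errors. A fully parameterised synthetic generator of death,
    population and gridded temperature data makes every stage testable
    without restricted vital-statistics microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
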