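Package: wardstaff
Title: Nurse Staffing Requirements from Patient Acuity Censuses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating ward nursing establishments from Safer
    Nursing Care Tool (SNCT) patient acuity/dependency censuses, quantifying
    the precision of establishment estimates by bootstrap resampling at
    varying audit lengths, and modelling nurse-reported staffing adequacy as
    a function of daily staffing shortfalls with three-level (day within
    unit within hospital) logistic regression.  Includes a calibrated
    synthetic ward-day generator for validating the whole pipeline by
    parameter recovery, data-cleaning rules for routinely collected
    staffing data (outlier days, unit reconfigurations, reverse-coded
    adequacy responses), and reporting helpers that produce study-style
    summary tables and figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
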