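Package: cvdrecal
Title: Recalibration of SCORE-Style 10-Year Fatal CVD Risk Charts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements the competing-risks recalibration method behind
    national 10-year fatal cardiovascular disease (CVD) risk charts.
    Baseline cause-specific mortality rates from national life-table counts
    are combined with population mean risk-factor levels and externally
    derived log hazard ratios for systolic blood pressure, cholesterol and
    smoking; individual 10-year risk is the cumulative incidence of CVD
    death under piecewise-constant cause-specific hazards over 5-year age
    bands, with non-CVD death as the competing event.  Includes chart grid
    tabulation and rendering, cell-wise chart comparison with intraclass
    correlation agreement, application to survey cohorts with weighted
    prevalence and mean-risk estimates, synthetic data generators with a
    Monte-Carlo lifetime simulator used as a correctness oracle, and CSV/JSON
    readers and writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
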