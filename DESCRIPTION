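Package: rhisits
Title: Interrupted Time Series Analysis of Routine Health Service Disruptions
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies pandemic-era disruptions to health services from
    routine health information system (RHIS/DHIS2-style) facility-month
    count data. Implements facility-level data cleaning (reporting
    completeness filter and high-outlier removal), aggregation to
    sub-national units, segmented interrupted time series regression by
    ordinary least squares with cluster-robust standard errors and
    small-sample t inference on G-2 degrees of freedom, percent-change
    effect estimates relative to the pre-pandemic baseline mean, and
    counterfactual estimation of cumulative missed care normalized per
    1,000 births or population. Includes a synthetic facility-panel
    generator with known ground truth so the whole pipeline is testable
    without access to restricted ministry-of-health data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
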