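Package: homingnav
Title: GPS Track Analysis for Homing-Pigeon Release Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the initial homing phase of GPS-tracked
    pigeon releases: track ingestion (CSV/GPX), escape-radius stripping,
    stop filtering and final-exit segmentation around the release site;
    four per-bird navigation metrics (virtual vanishing time, mean vector
    length of home-relative step directions, efficiency index and homing
    efficiency index); second-order circular summaries and two-sample
    Hotelling's T-squared comparisons of directional distributions; Type II
    ANOVA linear models with partial eta-squared, fitted mean differences
    and Cohen's d with noncentral-t confidence intervals; analytic
    noncentral-F power analysis; and a biased correlated random walk
    simulator that generates complete synthetic release studies for
    validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    car,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    geosphere,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
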