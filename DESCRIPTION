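Package: rqact
Title: Recurrence Quantification Analysis of Actigraphy Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify recurrent structure in wrist-actigraphy
    activity-count series and compare it between groups. Implements the
    preprocessing chain used in case-control actigraphy studies (non-wear
    trimming, 10-minute binning, length harmonisation, rank transform),
    recurrence plots thresholded at a fixed recurrence rate, seven
    recurrence quantifiers (determinism, laminarity, diagonal and vertical
    line-length means and entropies, and their ratio), the nonparametric
    circadian measures IS, IV and RA, and a group-comparison layer (Welch
    t, Cohen's d, Spearman correlation, logistic regression with McFadden
    pseudo R-squared, Bonferroni reporting). A synthetic cohort generator
    produces two-group actigraphy data with controllable bout duration and
    diversity so the full pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
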