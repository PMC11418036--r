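Package: gfryoung
Title: Validation of Creatinine-Based GFR Equations in Young Adults
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating and validating glomerular filtration rate
    (GFR) from serum creatinine in young adults. Implements the rescaled
    creatinine Q-value system, including age polynomials for a European
    reference population and a gradual-change interpolation for deriving
    race-free Q-values in new populations between ages 12 and 25; the EKFC,
    race-free CKD-EPI (2021) and re-expressed Lund-Malmo Revised equations;
    the standard validation metrics (median bias with bootstrap confidence
    intervals, interquartile range of the bias, P30/P20 accuracy) with a
    non-overlapping-confidence-interval comparison rule; age-trend summaries
    (median quantile regression, free-knot cubic splines, Bland-Altman
    agreement); a synthetic cohort generator calibrated to published cohort
    profiles; and an end-to-end validation pipeline producing stratified
    performance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
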