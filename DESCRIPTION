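Package: posthocsim
Title: Selection Bias in Post-Hoc Tests of Low-Powered Pre/Post Trials
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo machinery for two-arm pre/post randomized trials
    with a waitlist control. Simulates full parameter grids of trials,
    applies the standard analysis chain (2x2 group-by-time repeated-measures
    interaction test, Benjamini-Hochberg false discovery rate correction,
    within-arm paired t-tests conditioned on a significant interaction) and
    quantifies two selection artifacts: inflation of false-positive "change"
    findings in the untreated control arm when post-hoc tests are restricted
    to significant interactions (a Berkson-type collider effect), and
    winner's-curse inflation of detected effect sizes. Includes per-setting
    summaries, power-binned pooled rates, a sensitivity regression on the
    design parameters, and multi-start nonlinear curve fits relating
    statistical power to both artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
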