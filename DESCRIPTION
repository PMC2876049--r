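Package: milenorm
Title: Normative Age Ranges, Reliability, and Validation for Developmental
    Milestone Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for constructing and validating developmental screening
    instruments from binary milestone item responses. Fits per-item logistic
    age-of-attainment curves, screens their fit with the Hosmer-Lemeshow
    statistic and refits poorly fitting items with a triple-split piecewise
    logistic spline, inverts fitted curves to normative 25/50/75/90 percent
    attainment ages, scores children categorically (Denver-II-style two-failure
    rule over age-relevant items) and continuously, quantifies observer
    agreement with Cohen's kappa and percent agreement, applies consensus
    flagging rules for item removal, and evaluates construct validity against
    matched clinical comparison groups (McNemar and paired t tests,
    sensitivity and specificity with Wilson intervals). Includes a synthetic
    cohort generator with known true curves, a seven-consecutive-failure
    stopping rule, paired observer sessions, and shifted-ability clinical
    groups, so the whole pipeline is exercisable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
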