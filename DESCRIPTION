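Package: radsift
Title: Rule-Based Retrieval and Semi-Automated Abstraction of Radiology
    Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for semi-automated chart abstraction from free-text
    radiology reports. Provides a negation-aware Boolean, phrase and span
    query engine over an inverted index, editable rule sets that classify
    reports by image type, study indication and findings (built for
    lung-cancer surveillance imaging), an evaluation harness producing
    confusion matrices with sensitivity, specificity, positive predictive
    value and F1 plus exact and score confidence intervals, abstraction
    timing comparisons, and a seedable synthetic report generator that
    emulates a manually abstracted gold-standard cohort so the whole
    pipeline can be exercised without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
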