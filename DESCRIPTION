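Package: macbethvaf
Title: MACBETH Elicitation and Additive Value Frameworks for Therapy
    Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for multi-criteria value assessment of health
    technologies built on the MACBETH (Measuring Attractiveness by a
    Categorical Based Evaluation Technique) elicitation method.
    Qualitative pairwise attractiveness-difference judgments are
    converted into cardinal 0-100 value scales by linear programming,
    with consistency checking and minimal conflict-witness reporting.
    The package constructs direction-aware performance reference
    levels, piecewise-linear value functions, criterion weights by
    qualitative swing weighting, and additive value scores; it ships a
    nine-criterion value framework for lymphoma therapies, two-way
    random-effects intraclass correlation coefficients for rater-panel
    reliability, importance-score criteria selection, and seeded
    synthetic generators for judgment matrices, rater panels and drug
    performance tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    boot,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
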