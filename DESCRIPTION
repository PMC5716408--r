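Package: mddiff
Title: Modified Dose Difference and Gamma-Index Comparison of 2D Dose
    Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative comparison of two-dimensional radiotherapy dose
    distributions for patient-specific IMRT quality assurance.  Implements
    the modified dose difference (MDdiff) metric, a gradient-normalized
    dose difference that suppresses clinically insignificant discrepancies
    in high-dose-gradient regions, alongside a reference gamma-index
    implementation sharing the same dose-difference and
    distance-to-agreement criteria.  Includes synthetic IMRT-like planar
    dose field generation with controlled discrepancies (spatial shift,
    dose scaling, noise), per-case summary statistics, criteria sweeps,
    cohort trend analysis, a plain-text dose-grid interchange format, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
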