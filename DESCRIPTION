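Package: vigisignal
Title: Case/Non-Case Disproportionality Analysis for Spontaneous
    Adverse Event Reports
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Signal-detection pipeline for spontaneous pharmacovigilance
    databases of individual case safety reports (ICSRs). Provides a
    relational ICSR data model with lossless JSON-lines and delimited
    input/output, a five-level MedDRA-style term hierarchy with high-level
    term (HLT) to preferred term (PT) expansion, eligibility filtering with
    an exclusion audit trail and rule-based duplicate removal, 2x2
    contingency screening with the reporting odds ratio (ROR) and its 95%
    confidence interval under a minimum-case threshold, time-to-onset
    summaries and empirical cumulative distribution exports, descriptive
    cohort tables, and a fully parameterised synthetic ICSR database
    generator with planted drug-event odds ratios for end-to-end
    validation of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
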