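Package: forumlabs
Title: Mining and Validating Self-Reported Laboratory Results from Patient Forums
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for extracting clinical laboratory test results from
    patient-forum text and validating the resulting cohort against published
    study summaries. Includes a seeded synthetic-forum generator with ground
    truth, an embedding-based convolutional text screen for posts likely to
    contain laboratory results, rule-based extraction with unit inference and
    mistranscription checks, z-score quality control and cohort summaries, and
    two one-sided t-test (TOST) equivalence comparisons against literature
    cohorts using Cohen-d pooled-SD boundaries. Developed around
    polycystic ovary syndrome (PCOS) laboratory panels but parameterized by a
    test catalog.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
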