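Package: oncotext
Title: Rule-Based Oncology Text Mining with Federated Cohort Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for mining French-language cancer-care
    reports. Generates ground-truthed synthetic corpora of per-patient
    medical reports and hospital-discharge (PMSI-like) records, extracts
    medical concepts with a deterministic lexicon pipeline (negation and
    hypothesis context detection, concept-date linking), stores concept
    occurrences in a document-sourced pivot model, infers per-patient
    disease profiles including a weighted sliding-interval heuristic for
    dating metastasis onset, runs count-only federated cohort queries
    (notably the cancer-of-unknown-primary query), and evaluates cohort
    retrieval with recall, precision and F1.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
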