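Package: opioidphen
Title: Detecting Problematic Opioid Use in Clinical Notes with a Rule and
    SVM Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies documentation of problematic opioid use in free-text
    clinical notes. Extracts fixed-window snippets around a lexicon of
    opioid-related key phrases, classifies them with a four-tier sequential
    regular-expression voting system (absolute positive, canceling, general
    positive, neutral) and falls back to a linear support vector machine
    with lexically filtered n-gram and key-phrase-position features for
    snippets the rules abstain on. Also groups patients by opioid use
    disorder ICD-9/ICD-10 codes versus note-only identification, and
    compares the groups with chi-square and Welch t tests and absolute
    standardized differences with a greater-than-10-percent imbalance flag.
    Ships synthetic note-corpus and patient-cohort generators with recorded
    ground truth so the whole pipeline is testable without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
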