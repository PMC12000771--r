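Package: pregmorbid
Title: Morbidity Extraction and Multimorbidity Analysis for Semi-Structured Maternity Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning semi-structured free-text condition fields from
    routinely collected maternity records into analysable morbidity profiles,
    and for the downstream epidemiological analyses built on them. Provides a
    keyword-lexicon extractor with text normalisation and Levenshtein fuzzy
    matching, derivation of BMI and maternal-age risk categories, multimorbidity
    burden summaries, continuity-corrected chi-square and phi-coefficient
    association screening of morbidities against pregnancy complications, and
    k-means comorbidity phenotyping with elbow-based cluster-number selection
    and per-cluster gestational diabetes risk. A seeded synthetic-cohort
    generator with recoverable ground truth makes every stage testable without
    access to real medical records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
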