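Package: bmtoolkit
Title: Checklist-Based Scoring of Cancer Biomarker Reporting Completeness
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how completely cancer-biomarker
    publications report the attributes associated with successful clinical
    translation. Provides a versioned hierarchical checklist model
    (categories, sub-categories, attributes), binary per-publication
    scoring with category averaging and a study-type amendment of the
    clinical-utility score, biomarker-level aggregation to total
    percentage scores with gap reports, Delphi consensus analysis
    (agreement thresholds, two-round retention, rank-derived category
    weights), exact and tie-corrected Mann-Whitney U comparison of
    successful versus stalled biomarker groups, logistic and Cox
    association models, a synthetic-corpus generator for power analysis,
    and a reproducible end-to-end pipeline with corpus-ledger
    bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
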