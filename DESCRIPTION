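Package: annodrift
Title: Retrospective Analysis of Protein Functional-Annotation Drift Across
    Knowledgebase Releases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how protein functional annotation evolves
    across versioned releases of a curated protein knowledgebase. Reads and
    writes a compact XML release dialect modelled on document-oriented
    knowledgebase dumps, generates seeded synthetic release series with
    controlled annotation accrual and removal, diffs releases (protein
    existence counts, removed-function cases, newly annotated proteins),
    partitions controlled-vocabulary terms into recently more or less
    frequently detected subsets, scales term frequencies for tag-cloud
    export, and classifies the temporal order in which protein binding
    versus other functions were first published from experimental evidence
    and publication dates.
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
    tibble,
    withr,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
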