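Package: soles
Title: Curation Engine for Systematic Online Living Evidence Summaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and maintaining a systematic online living
    evidence summary (SOLES) of a research literature: ingest, normalisation,
    merge and deduplication of bibliographic citation records (RIS,
    MEDLINE/PubMed XML, CSV); compilation of term lists into boundary-anchored,
    variant-expanded regular-expression dictionaries for tagging studies by
    animal model, intervention, outcome measure, species and sex; extraction of
    model-description sentences from full texts; multi-field frequency-threshold
    tagging policies; a validation harness that scores tagging methods against
    human TRUE/FALSE annotations and selects an optimal policy; evaluation of
    screening classifiers with per-run performance logging; evidence-map
    reporting (per-year counts, tag coverage, co-occurrence cross-tabulations,
    Boolean filtered exports); and a synthetic-corpus generator with planted
    ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    xml2,
    yaml,
    glmnet,
    Matrix,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
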