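Package: taxacade
Title: Taxonomic Backbone Matching and Checklist Impact Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating expert-curated taxonomic
    checklists of the kind aggregators such as GBIF use to interpret
    occurrence records. Reads and writes checklists as Darwin Core Archives
    and as the 19-field working spreadsheet format used in collaborative
    checklist curation; parses verbatim scientific names into canonical
    components and authorship; indexes a checklist into a validated backbone
    with synonym resolution and hierarchical fallback; implements the
    name-interpretation cascade (exact, fuzzy, synonym resolution,
    higher-rank fallback on no-match or ambiguity); computes checklist
    summaries, two-version diffs, backbone name-overlap accounting, and
    occurrence rank-improvement impact reports; and generates synthetic
    checklists, degraded backbone pairs, and corrupted occurrence streams
    with analytic ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
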