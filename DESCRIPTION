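Package: hybridcurate
Title: Hybrid Curation of Gene-Mutation Relations from Abstracts
Version: 1.0.0
Author: Package Author
Maintainer: Package Author <author@example.org>
Description: Tools for hybrid literature curation of point-mutation findings:
    pattern-based extraction and standardization of mutation mentions from
    MEDLINE titles and abstracts, gazetteer gene tagging with
    abbreviation-resolution filtering against a human gene lexicon,
    construction of candidate gene-mutation relation items for redundant
    human (or simulated-crowd) judgment, Naive Bayes aggregation of
    judgments weighted by control-item performance, and an evaluation
    framework covering entity-level and relation-level precision and
    recall, pairwise agreement statistics, and cost-accuracy tradeoffs.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
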