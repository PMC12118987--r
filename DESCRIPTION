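Package: depscreen
Title: Depression Screening from Clinical Interview Transcripts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for screening depression from timed
    clinical-interview transcripts in the DAIC-WOZ style. Parses
    tab-separated turn transcripts and PHQ-8 label tables, cleans and
    tokenizes utterances, computes a 30-feature bank (19 per-question
    answer-sentiment features plus 11 global speech and lexical features),
    runs exhaustive feature-subset by hyperparameter searches over random
    forest, gradient-boosted-tree and support-vector-machine classifiers,
    and selects models by accuracy subject to a minority-class F1
    constraint. Includes a synthetic corpus generator with known planted
    class effects so the whole pipeline is testable without access to the
    restricted interview corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    ranger,
    stats,
    tibble,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
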