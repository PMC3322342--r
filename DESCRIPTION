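Package: gscatlas
Title: Cross-Dataset Filtering of Germline Stem Cell Niche Expression
    Profiles
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for identifying genes
    enriched in germline stem cells (GSCs), somatic niche cells, and
    differentiating germ cells of the Drosophila gonad by integrating a
    two-color germarium vs testis-apex tissue comparison with two
    single-channel stem-cell-enriched datasets. Provides a seeded
    synthetic-data generator with planted ground truth (population
    expression atlas, tissue mixtures, two-color arrays with dye swaps
    and intensity-dependent dye bias, two-group single-channel sets),
    MA-plot loess and quantile normalization, an empirical-Bayes
    moderated t-test with Benjamini-Hochberg false discovery rate
    control, conjunctive significance/direction/intensity filters with
    rank-sum ordering of candidate gene lists, hypergeometric term
    over-representation analysis, and precision/recall evaluation of
    list recovery against the planted truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    limma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
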