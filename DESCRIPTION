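Package: tfgo
Title: Transcription-Factor-Centric Differential Expression and GO Enrichment Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for a transcription-factor-centric analysis of two-group
    microarray experiments. Implements probe-level preprocessing (negative
    clamping, 75th-percentile normalization, detection-flag filtering),
    moderated t-statistics with empirical-Bayes variance shrinkage and
    Benjamini-Hochberg control, classic score-based Kolmogorov-Smirnov
    enrichment over a Gene Ontology DAG run separately on up- and
    down-regulated streams, two orderings of the enrichment and
    transcription-factor selection steps, order-weighted word-significance
    mining of ontology labels, keyword-driven term curation, and a
    synthetic-data generator with planted differential expression and
    planted term enrichment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
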