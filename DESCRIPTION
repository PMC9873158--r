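Package: dietoverlap
Title: Diet Composition, Niche Overlap and Feeding-Strategy Analysis for
    Stream Fishes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for stomach-content (diet count) analysis of stream
    fishes: ingestion and validation of per-fish prey-count tables,
    taxonomy-level aggregation, pooled diet compositions, Pianka's index
    of niche overlap, Amundsen-Costello feeding-strategy statistics
    (frequency of occurrence and prey-specific abundance), prey-item
    richness summaries, and quasi-binomial logit models of per-category
    consumption with QAICc model selection and back-transformed
    predicted proportions.  Includes a Dirichlet-multinomial diet
    simulator that emulates a two-species, two-stream salmonid study
    design so the full pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
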