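Package: traitspace
Title: Data-Driven Localization of Questionnaire Traits with Network and
    Embedding Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for placing psychometric traits and their
    questionnaire items in a common "trait space": keyed scoring and
    standardization of multi-instrument Likert surveys, internal-consistency
    reliability (Cronbach's alpha, split-half), correlation-distance
    hierarchical clustering of traits and subjects (WPGMA), PC-stable
    partial-correlation graph learning with Fisher-z conditional-independence
    tests, MDS-initialized t-SNE embedding of all items, embedding-based item
    refinement of a target scale via linear-separability screening, two-way
    factorial analysis of dichotomized trait groups, and a synthetic-cohort
    generator with planted trait-cluster, subject-group and item-subdomain
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    e1071,
    igraph,
    ape,
    vegan
Suggests:
    testthat (>= 3.0.0),
    car,
    MASS,
    withr,
    mclust,
    cluster,
    optparse
Config/testthat/edition: 3
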