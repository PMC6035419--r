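Package: sublangr
Title: Sublanguage Pattern Mining for Clinical Report Knowledge Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A data-driven sublanguage analysis pipeline that turns a corpus of
    domain-restricted report text (such as radiology image reports) with
    constituency parses and a semantic lexicon into a knowledge model. Report
    text is segmented into short clauses, Subject:Relationship:Object triples
    are extracted from Penn-Treebank parse trees via embedded verb- and
    preposition-phrase patterns, entity phrases are tagged with one semantic
    type each using a pluggable lexicon and a last-recognizable-entity rule,
    a directed co-occurrence network over semantic types is induced and pruned,
    types are regrouped into coarse semantic categories, and relationship
    labels are attached to form a knowledge model. Includes annotation
    evaluation metrics (one-vs-rest precision/recall/F, relationship coverage,
    inter-rater agreement) and a deterministic synthetic-corpus generator with
    gold annotations for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
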