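Package: litmine
Title: Desk-Scale Biomedical Literature Mining for Target-Disease-Drug Evidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A testable, desk-scale pipeline for extracting drug-target evidence
    from biomedical text. Tags gene/protein, disease, chemical/drug and organism
    mentions with a gazetteer (dictionary) tagger, evaluates tagging against gold
    spans under strict and partial span-matching modes, grounds mentions to
    ontology-style lexicon identifiers through a lexical cascade backed by
    skip-gram word embeddings, extracts and ranks same-sentence co-occurrence
    associations, and reports corpus-level normalization and benchmark
    statistics. Ships a synthetic-corpus generator with planted gold spans and
    known true associations so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stringi,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
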