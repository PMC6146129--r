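Package: ppimx
Title: Extraction of Mutation-Affected Protein-Protein Interactions from
    Biomedical Abstracts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Document-level extraction of protein-protein interactions
    affected by genetic mutations (PPIm) from article titles and abstracts.
    Implements a three-stage pipeline: a character-CNN + bidirectional LSTM
    gene-mention tagger trained on IOB1 sequences with ensemble probability
    averaging and a lexicon-based recall post-processor; knowledge-based
    normalization of mentions to gene identifiers using ranked name lookups
    restricted by document-level gene sets with a secondary fallback source;
    and an entity-blinded multi-window convolutional relation classifier with
    ensemble scoring, a 50% decision threshold and a single-best fallback
    prediction. Includes PubTator-style corpus input/output, micro and macro
    precision/recall/F1 evaluation under exact and homology-group gene
    matching, and a deterministic synthetic-fixture generator for offline
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
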