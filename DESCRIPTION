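Package: defner
Title: Entity-Definition-Enhanced Biomedical Named Entity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Span-based biomedical named entity recognition enhanced with
    entity-type definition information, for clinical text corpora in BRAT
    standoff format.  Implements two formulations: a machine-reading-
    comprehension (MRC) model in which each entity type's definition text is
    packed with the sentence as a query, and a span-level one-pass (SOne)
    model in which a fixed-dimension definition vector is concatenated to
    every token representation before typed boundary prediction.  Includes
    BRAT corpus reading and writing, sentence splitting, token/character
    offset alignment, start/end span decoding, strict exact-match
    micro-averaged precision/recall/F1 evaluation, a synthetic clinical-style
    corpus generator, and a small trainable self-attention encoder so the
    full pipeline is testable on a single CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
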