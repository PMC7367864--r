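Package: synthactions
Title: Extraction of Structured Synthesis Actions from Experimental Procedure Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts free-text chemical synthesis procedures, as written in
    patents and experimental sections, into structured sequences of synthesis
    actions (Add, Stir, Concentrate, ...). Provides the action data model with
    per-type allowed properties and validation, a bijective single-line textual
    representation of action sequences, a rule-based natural-language extractor
    built on a verb lexicon with context disambiguation and implicit-action
    insertion, corpus construction utilities (legacy-record adaptation, source
    combination, pretraining filters, splits, hard-sentence selection),
    entity-substitution data augmentation, an evaluation metric suite
    (validity, adapted BLEU, normalized Levenshtein similarity, threshold
    accuracies, per-type confusion ledger), a seeded synthetic-procedure
    generator with exact ground truth, and a scaled-down pretrain-and-refine
    sequence-to-sequence translation protocol with beam n-best decoding and
    ensembling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
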