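Package: mnpner
Title: Named Entity Recognition for Marine Natural Product Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising typed entity mentions (compound names,
    molecular formulas, taxonomic names, sample sources, bioactivities) in
    marine natural product literature. Implements corpus construction from
    raw text (sentence splitting, entity-type indexing, character-offset
    resolution, BIO tagging, CoNLL-style I/O), a seeded synthetic corpus
    generator with gold annotations, a neural sequence tagger combining
    word and character features, iterated dilated convolutions and a
    document-level attention layer over a linear-chain conditional random
    field, with exact forward/Viterbi inference, training, prediction, and
    an exact-match span evaluation protocol with ablation support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
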