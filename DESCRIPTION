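Package: emrner
Title: Clinical Named-Entity Recognition for Chinese Electronic Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-level clinical named-entity recognition for Chinese
    electronic medical record (EMR) notes. Implements the three classical
    model families used for this task -- dictionary maximum string matching,
    a feature-based linear-chain conditional random field (CRF) trained by
    penalized maximum likelihood with forward-backward inference and Viterbi
    decoding, and a bidirectional peephole-LSTM encoder with a constrained
    CRF output layer -- together with BIO sequence conversion, windowed
    unigram feature templates (part of speech, radical, document type,
    character index), strict and relaxed entity-matching evaluation,
    inter-annotator agreement, and a seeded generator of synthetic annotated
    EMR corpora for the seven entity types found in neurosurgical admission
    notes (symptom, body region, disease, family history, surgery,
    medication, disease course).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
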