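Package: ontoStream
Title: Zero-Shot Extension of Hierarchical Symptom Ontologies from Streaming Forum Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Grows an existing hierarchical symptom ontology from a stream of
    patient-forum sentences using an online clustering loop driven by six
    cooperating agent roles (symptom identification, extraction,
    classification, duplication checking, relation generation and relation
    verification). Agent roles are served either by a pluggable large
    language model backend carrying role-specific prompts, or by a
    deterministic lexicon oracle for fully offline, reproducible runs.
    Includes a masked-symptom-recovery evaluation protocol based on
    normalized Levenshtein fuzzy matching with per-category precision,
    recall and F1, ablation and baseline runners, and a synthetic
    forum-corpus generator with exact ground-truth annotations.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
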