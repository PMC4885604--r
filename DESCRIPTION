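Package: metminer
Title: Text Mining of Metastasis Concepts, Relations and Networks from
    Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("MET", "Maintainers", email = "metminer@example.org",
           role = c("aut", "cre"))
Description: Extracts metastasis-related concept mentions, binary
    relations and composed regulation/metastasis events from biomedical
    abstracts, and assembles the results into evidence-backed networks
    that can be integrated across documents.  Concept recognition is
    dictionary based (nine concept types covering genes, microRNAs,
    metastasis processes, cancers, organs and tissues) with a rule-based
    microRNA recognizer; relation extraction matches configurable slot
    patterns over concept-type and trigger-class tags.  Includes BioC XML
    and curation-table I/O, a precision/recall evaluation harness with
    gold concept boundaries, a synthetic-corpus generator with planted
    gold annotations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
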