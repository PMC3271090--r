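Package: ontomine
Title: Ontology-Based Gene Annotation Mining from Gene-Centric Text
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines candidate gene annotations from gene-centric free text
    (e.g. one encyclopedia-style article per gene) by dictionary-based
    recognition of ontology term labels. Loads OBO ontologies into typed
    directed acyclic graphs with configurable subsumption relations,
    cleans wiki markup and segments sentences, recognizes preferred term
    labels with longest whole-word matching, classifies candidate
    annotations against reference annotation sets as exact, more-specific,
    more-general or novel via ontology lineage, estimates precision bounds
    from manual-evaluation tallies, and quantifies the value of mined
    annotations in controlled Fisher-exact gene-set enrichment experiments
    with a random-gene-set null simulation. Includes seeded generators for
    toy ontologies, planted-mention corpora, noisy reference sets and
    enrichment scenarios so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
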