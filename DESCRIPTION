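Package: hoipr
Title: Homeostasis-Imbalance Process Ontologies for Cellular Senescence
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A toolkit for homeostasis-imbalance process ontologies of
    cellular senescence mechanisms. Provides a typed in-memory model of
    OWL-DL course/process ontologies restricted to named subsumption and
    existential restrictions, readers and writers for Turtle and RDF/XML,
    a materializing reasoner for transitive causal relations, inverse
    properties and the has-part-result property chain, course-scoped
    causal queries (causes, results, paths, cross-course inference,
    generalized networks), a four-stage homeostatic-imbalance pattern
    checker, and network exporters (SIF, GraphML, CX) with the styling
    conventions used for senescence course visualization. Ships a curated
    cellular-senescence demonstration ontology and a seeded random
    ontology generator with an independently computed closure for
    property-based testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, xml2, jsonlite, igraph
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, Annotation, GraphAndNetwork, Network
RoxygenNote: 7.3.3
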