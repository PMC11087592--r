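## Shared fixture builders for the test suite.

## quick document from an axiom table; terms are auto-declared as
## processes unless listed in `kinds`
quickDoc <- function(axioms, kinds = character(0), relations = NULL) {
    ids <- sort(unique(c(axioms$subject, axioms$object)))
    terms <- data.frame(id = ids, label = ids,
                        entity_kind = ifelse(ids %in% names(kinds),
                                             unname(kinds[ids]), "process"),
                        stringsAsFactors = FALSE)
    if (is.null(relations)) relations <- canonicalRelationRegistry()
    makeOntologyDocument(terms = terms, relations = relations, axioms = axioms)
}

subAx <- function(s, o) {
    data.frame(subject = s, kind = "subclass_of", relation = NA_character_,
               object = o, provenance = "asserted", stringsAsFactors = FALSE)
}

exAx <- function(s, r, o) {
    data.frame(subject = s, kind = "existential", relation = r, object = o,
               provenance = "asserted", stringsAsFactors = FALSE)
}

chainAx <- function(ids, relation = "has_result") {
    do.call(rbind, lapply(seq_len(length(ids) - 1L), function(i)
        exAx(ids[i], relation, ids[i + 1L])))
}

## closure edge table of a materialized graph, comparable with
## bruteForceClosure() / randomOntology()$closure
matEdges <- function(graph) {
    e <- inferredEdges(graph)[, c("subject", "relation", "object")]
    e <- e[order(e$subject, e$relation, e$object), , drop = FALSE]
    rownames(e) <- NULL
    e
}

hasEdge <- function(graph, s, r, o) entails(graph, s, r, o)$entailed

## the curated ontology and its closure, computed once per test run
fixtureDoc <- senescenceOntology()
fixtureGraph <- materialize(fixtureDoc)
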