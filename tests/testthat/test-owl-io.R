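test_that("a hand-written Turtle causal restriction is captured as an existential axiom", {
    ttl <- paste(
        '@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .',
        '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
        '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
        '@prefix HOIP: <http://purl.bioontology.org/ontology/HOIP/> .',
        '@prefix hoipv: <https://w3id.org/hoipr/vocab#> .',
        'HOIP:HOIP0060102 a owl:Class ;',
        '    rdfs:label "SASP secretion" ;',
        '    rdfs:subClassOf [ a owl:Restriction ;',
        '        owl:onProperty hoipv:has_result ;',
        '        owl:someValuesFrom HOIP:HOIP0060113 ] .',
        'HOIP:HOIP0060113 a owl:Class ; rdfs:label "chronic inflammation" .',
        sep = "\n")
    res <- readOntology(ttl, format = "turtle", fromText = TRUE)
    ax <- ontoAxioms(res$document)
    expect_identical(nrow(ax), 1L)
    expect_identical(ax$subject, "HOIP:0060102")
    expect_identical(ax$relation, "has_result")
    expect_identical(ax$object, "HOIP:0060113")
    expect_identical(res$report@accepted_axioms, 1L)
    expect_length(res$report@dangling_refs, 0L)
})

test_that("class declarations without axioms parse to terms and an empty axiom list", {
    ttl <- paste(
        '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
        '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
        '@prefix HOIP: <http://purl.bioontology.org/ontology/HOIP/> .',
        'HOIP:HOIP0060024 a owl:Class ; rdfs:label "cellular senescence course" .',
        'HOIP:HOIP0060129 a owl:Class .',
        sep = "\n")
    res <- readOntology(ttl, format = "turtle", fromText = TRUE)
    expect_identical(nrow(ontoTerms(res$document)), 2L)
    expect_identical(nrow(ontoAxioms(res$document)), 0L)
})

test_that("unsupported constructs are skipped and reported, not silently dropped", {
    ttl <- paste(
        '@prefix owl: <http://www.w3.org/2002/07/owl#> .',
        '@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .',
        '@prefix HOIP: <http://purl.bioontology.org/ontology/HOIP/> .',
        '@prefix hoipv: <https://w3id.org/hoipr/vocab#> .',
        'HOIP:HOIP0000001 a owl:Class ;',
        '    rdfs:subClassOf [ a owl:Restriction ;',
        '        owl:onProperty hoipv:has_result ;',
        '        owl:allValuesFrom HOIP:HOIP0000002 ] ;',
        '    rdfs:subClassOf [ a owl:Restriction ;',
        '        owl:onProperty hoipv:has_result ;',
        '        owl:someValuesFrom [ a owl:Restriction ;',
        '            owl:onProperty hoipv:has_part ;',
        '            owl:someValuesFrom HOIP:HOIP0000003 ] ] ;',
        '    rdfs:subClassOf HOIP:HOIP0000002 .',
        'HOIP:HOIP0000002 a owl:Class .',
        sep = "\n")
    res <- readOntology(ttl, format = "turtle", fromText = TRUE)
    expect_identical(res$report@accepted_axioms, 1L)  # only the named subsumption
    skipped <- res$report@skipped_constructs
    expect_true(any(grepl("allValuesFrom", skipped$construct)))
    expect_true(any(grepl("anonymous", skipped$construct)))
})

test_that("reading and writing round-trips terms, relations and axioms in both formats", {
    docs <- list(curated = fixtureDoc,
                 random = randomOntology(nClasses = 18, seed = 5)$document)
    for (nm in names(docs)) {
        for (fmt in c("turtle", "rdfxml")) {
            txt <- writeOntology(docs[[nm]], format = fmt)
            back <- readOntology(txt, format = fmt, fromText = TRUE)
            expect_true(hoipr:::sameOntology(docs[[nm]], back$document),
                        label = paste(nm, fmt, "round-trip"))
            ## parsing is deterministic byte-for-byte
            again <- readOntology(txt, format = fmt, fromText = TRUE)
            expect_identical(ontoAxioms(back$document),
                             ontoAxioms(again$document))
            expect_identical(back$report@skipped_constructs,
                             again$report@skipped_constructs)
        }
    }
})

test_that("a registry-only document serializes its property chain declaration", {
    doc <- makeOntologyDocument(relations = canonicalRelationRegistry())
    ttl <- writeOntology(doc, format = "turtle")
    expect_match(ttl, "propertyChainAxiom")
    expect_match(ttl, "TransitiveProperty")
    expect_match(ttl, "inverseOf")
    back <- readOntology(ttl, format = "turtle", fromText = TRUE)
    rel <- ontoRelations(back$document)
    expect_identical(rel$chain1[rel$id == "has_part_result"], "has_part")
    expect_identical(rel$chain2[rel$id == "has_part_result"], "has_result")
    ## empty document still yields a valid header-only serialization
    empty <- makeOntologyDocument(relations = canonicalRelationRegistry()[0, ])
    res <- readOntology(writeOntology(empty, format = "rdfxml"),
                        format = "rdfxml", fromText = TRUE)
    expect_identical(nrow(ontoTerms(res$document)), 0L)
})

test_that("malformed input raises a parse error", {
    expect_error(readOntology("HOIP:xyz <unterminated", format = "turtle",
                              fromText = TRUE), "parse error")
    expect_error(readOntology("<notxml", format = "rdfxml", fromText = TRUE))
    expect_error(readOntology("/no/such/file.ttl", format = "turtle"),
                 "not found")
})

test_that("an independent RDF library parses the Turtle output with the expected triple count", {
    py <- Sys.which("python")
    expect_true(nzchar(py))
    path <- tempfile(fileext = ".ttl")
    writeOntology(fixtureDoc, path = path, format = "turtle")
    out <- system2(py, c("-c", shQuote(paste0(
        "import rdflib; g = rdflib.Graph(); g.parse('", path,
        "', format='turtle'); print(len(g))"))), stdout = TRUE)
    expected <- nrow(hoipr:::documentToTriples(fixtureDoc)) + 1L  # + root-class note
    expect_identical(as.integer(out[length(out)]), expected)
})
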