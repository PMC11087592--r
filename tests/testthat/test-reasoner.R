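test_that("transitive causal reasoning reaches indirect causes (p21 chain)", {
    doc <- quickDoc(chainAx(c("X:ATM", "X:P53", "X:REGP53", "X:P21")))
    g <- materialize(doc)
    expect_true(hasEdge(g, "X:ATM", "has_result", "X:P21"))
    expect_true(hasEdge(g, "X:ATM", "has_result", "X:REGP53"))
    ## inverse coherence of the same entailment
    expect_true(hasEdge(g, "X:P21", "has_cause", "X:ATM"))
    ## asserted axioms come back with a single-step derivation
    d <- entails(g, "X:ATM", "has_result", "X:P53")
    expect_true(d$entailed)
    expect_length(d$derivation, 1L)
    expect_match(d$derivation, "^asserted")
    ## inferred edges carry a rule-tagged derivation
    d2 <- entails(g, "X:ATM", "has_result", "X:P21")
    expect_gt(length(d2$derivation), 1L)
    expect_match(d2$derivation[1L], "^R4")
})

test_that("the has-part-result property chain composes part-whole with causation", {
    ax <- rbind(exAx("X:DDR", "has_part", "X:ATR"),
                exAx("X:DDR", "has_part", "X:ATM"),
                chainAx(c("X:ATM", "X:P53", "X:REGP53", "X:P21")),
                exAx("X:ATR", "has_result", "X:P53"))
    g <- materialize(quickDoc(ax))
    expect_true(hasEdge(g, "X:DDR", "has_part_result", "X:P21"))
    expect_true(hasEdge(g, "X:DDR", "has_part_result", "X:P53"))
    ## ATR and ATM are upstream of p21 through the causal relation
    expect_true(all(c("X:ATM", "X:ATR") %in% causesOf(g, "X:P21")))
    ## the chain fires on entailed, not only asserted, causal edges
    d <- entails(g, "X:DDR", "has_part_result", "X:P21")
    expect_match(d$derivation[1L], "^R5")
})

test_that("degenerate inputs behave: empty document, single edge, chain config error", {
    g0 <- materialize(makeOntologyDocument())
    expect_identical(nrow(inferredEdges(g0)), 0L)
    expect_identical(nrow(bruteForceClosure(makeOntologyDocument())), 0L)

    g1 <- materialize(quickDoc(exAx("A:1", "has_result", "A:2")))
    e1 <- matEdges(g1)
    expect_identical(e1[e1$relation == "has_result", "subject"], "A:1")
    expect_identical(nrow(e1), 2L)   # the edge and its inverse, nothing else

    badreg <- canonicalRelationRegistry()
    badreg$chain1[badreg$id == "has_part_result"] <- "no_such_relation"
    expect_error(materialize(quickDoc(exAx("A:1", "has_result", "A:2"),
                                      relations = badreg)),
                 "undeclared relation")
})

test_that("a pure causal path of n processes closes to n(n+1)/2 edges", {
    for (n in c(4L, 10L)) {
        ids <- sprintf("P:%03d", seq_len(n + 1L))
        g <- materialize(quickDoc(chainAx(ids)))
        e <- matEdges(g)
        expect_identical(sum(e$relation == "has_result"), (n * (n + 1L)) %/% 2L)
        expect_identical(sum(e$relation == "has_cause"), (n * (n + 1L)) %/% 2L)
    }
})

test_that("causal cycles terminate and entail every ordered pair", {
    ax <- rbind(exAx("C:1", "has_result", "C:2"),
                exAx("C:2", "has_result", "C:3"),
                exAx("C:3", "has_result", "C:1"))
    g <- materialize(quickDoc(ax))
    for (s in c("C:1", "C:2", "C:3")) {
        for (o in c("C:1", "C:2", "C:3")) {
            expect_true(hasEdge(g, s, "has_result", o), label = paste(s, o))
        }
    }
    ## self-causes never arise on acyclic graphs
    ga <- materialize(quickDoc(chainAx(c("A:1", "A:2", "A:3"))))
    expect_false(hasEdge(ga, "A:1", "has_result", "A:1"))
})

test_that("materialization is idempotent and monotone", {
    r <- randomOntology(nClasses = 20, seed = 42, cycles = 1)
    g1 <- materialize(r$document)
    ## re-materializing the same document adds nothing
    expect_identical(matEdges(materialize(r$document)), matEdges(g1))
    ## adding an axiom never removes an entailed edge
    doc2 <- makeOntologyDocument(
        terms = ontoTerms(r$document),
        relations = ontoRelations(r$document),
        axioms = rbind(ontoAxioms(r$document),
                       exAx("RND:0000001", "has_result", "RND:0000020")))
    e1 <- matEdges(g1); e2 <- matEdges(materialize(doc2))
    k <- function(e) paste(e$subject, e$relation, e$object)
    expect_true(all(k(e1) %in% k(e2)))
})

test_that("engine, brute-force oracle and constructive ground truth agree on random ontologies", {
    for (s in 1:25) {
        r <- randomOntology(nClasses = 10 + (s * 7) %% 31, seed = s,
                            cycles = s %% 3, chainDensity = 0.4)
        m <- matEdges(materialize(r$document))
        expect_identical(m, r$closure, label = paste("truth seed", s))
        expect_identical(m, bruteForceClosure(r$document),
                         label = paste("oracle seed", s))
    }
})

test_that("inverse coherence and duality hold across the closure", {
    r <- randomOntology(nClasses = 25, seed = 99, cycles = 2)
    g <- materialize(r$document)
    e <- matEdges(g)
    res <- e[e$relation == "has_result", ]
    cau <- e[e$relation == "has_cause", ]
    expect_setequal(paste(res$subject, res$object), paste(cau$object, cau$subject))
    prt <- e[e$relation == "has_part", ]
    pof <- e[e$relation == "part_of", ]
    expect_setequal(paste(prt$subject, prt$object), paste(pof$object, pof$subject))
})

test_that("the brute-force oracle refuses documents beyond its size guard", {
    big <- makeOntologyDocument(
        terms = data.frame(id = sprintf("B:%04d", 1:250),
                           entity_kind = "process"))
    expect_error(bruteForceClosure(big), "refusing")
})

test_that("entailment queries reject unknown classes", {
    expect_error(entails(fixtureGraph, "HOIP:9999999", "has_result",
                         "HOIP:0060427"), "unknown class")
})
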