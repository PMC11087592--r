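test_that("the relation registry carries the published logical characteristics", {
    reg <- canonicalRelationRegistry()
    at <- function(id) reg[reg$id == id, , drop = FALSE]
    expect_true(at("has_result")$transitive)
    expect_true(at("has_cause")$transitive)
    expect_false(at("has_part")$transitive)   # only the causal pair is
    expect_identical(at("has_cause")$inverse_of, "has_result")
    expect_identical(at("has_result")$inverse_of, "has_cause")
    expect_identical(at("has_part")$inverse_of, "part_of")
    expect_identical(c(at("has_part_result")$chain1, at("has_part_result")$chain2),
                     c("has_part", "has_result"))
    expect_identical(at("realizes_disease")$domain_kind, "process")
    expect_identical(at("realizes_disease")$range_kind, "disease")
    expect_identical(at("manifests_symptom")$range_kind, "symptom")
    expect_identical(at("has_role")$range_kind, "role")
    ## closed under inverses with mirrored characteristics
    for (i in seq_len(nrow(reg))) {
        iv <- reg$inverse_of[i]
        if (is.na(iv)) next
        j <- match(iv, reg$id)
        expect_false(is.na(j))
        expect_identical(reg$inverse_of[j], reg$id[i])
        expect_identical(reg$transitive[j], reg$transitive[i])
    }
    ## configurable part-whole transitivity
    expect_true(canonicalRelationRegistry(partTransitive = TRUE)[
        reg$id == "has_part", "transitive"][1])
})

test_that("domain/range violations and dangling references are reported as data", {
    ax <- rbind(exAx("P:1", "realizes_disease", "P:2"),   # range violation
                exAx("D:1", "realizes_disease", "D:2"),   # domain violation
                exAx("P:1", "has_result", "P:3"))
    doc <- quickDoc(ax, kinds = c("D:1" = "disease", "D:2" = "disease"))
    rep <- validateDocument(doc)
    expect_identical(sort(unique(rep$type)),
                     c("domain_violation", "range_violation"))
    expect_identical(rep$subject[rep$type == "range_violation"], "P:1")

    dangle <- makeOntologyDocument(
        terms = data.frame(id = "P:1", entity_kind = "process"),
        axioms = exAx("P:1", "has_result", "P:9"))
    rep2 <- validateDocument(dangle)
    expect_true("dangling_reference" %in% rep2$type)
    expect_true("P:9" %in% rep2$subject)
})

test_that("documents produced by the fixture generators validate cleanly", {
    expect_identical(nrow(validateDocument(fixtureDoc)), 0L)
    for (s in c(3L, 11L)) {
        r <- randomOntology(nClasses = 15, seed = s)
        expect_identical(nrow(validateDocument(r$document)), 0L)
    }
})

test_that("structurally invalid documents are rejected at construction", {
    expect_error(makeOntologyDocument(
        terms = data.frame(id = "P:1", entity_kind = "process"),
        axioms = exAx("P:1", "has_result", "P:1")),
        "self-causal")
    expect_error(makeOntologyDocument(
        terms = data.frame(id = c("P:1", "P:1"), entity_kind = "process")),
        "duplicated")
})
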