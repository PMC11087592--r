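test_that("stage assignment is idempotent, conflict-checked and forceable", {
    doc <- quickDoc(chainAx(c("S:1", "S:2", "S:3", "S:4")))
    doc <- assignStage(doc, "S:1", "stress_demand")
    expect_identical(unname(stageTags(doc)["S:1"]), "stress_demand")
    ## same stage again: no-op
    expect_identical(stageTags(assignStage(doc, "S:1", "stress_demand")),
                     stageTags(doc))
    ## different stage: conflict unless forced
    expect_error(assignStage(doc, "S:1", "outcome"), "already carries")
    doc2 <- assignStage(doc, "S:1", "outcome", force = TRUE)
    expect_identical(unname(stageTags(doc2)["S:1"]), "outcome")
    expect_error(assignStage(doc, "S:9", "outcome"), "unknown process")
})

test_that("the heuristic pre-tagger suggests demand and response stages but never overwrites", {
    ax <- rbind(subAx("H:RESP1", "H:RESPROOT"),
                exAx("H:DEMAND1", "has_result", "H:RESP1"))
    doc <- quickDoc(ax)
    doc@terms$label[doc@terms$id == "H:DEMAND1"] <-
        "increasing demand for the oncogenic stress response"
    doc <- assignStage(doc, "H:RESPROOT", "imbalance")  # pre-existing tag
    tagged <- preTagStages(doc, responseRoot = "H:RESPROOT")
    tags <- stageTags(tagged)
    expect_identical(unname(tags["H:DEMAND1"]), "stress_demand")
    expect_identical(unname(tags["H:RESP1"]), "stress_response")
    expect_identical(unname(tags["H:RESPROOT"]), "imbalance")  # untouched
})

test_that("embryonic, acute and chronic courses satisfy the four-stage pattern with a causal witness", {
    for (course in c("HOIP:0060267", "HOIP:0060196", "HOIP:0060195")) {
        rep <- checkCoursePattern(fixtureGraph, course)
        expect_length(rep@missing, 0L)
        expect_setequal(rep@stages_present, imbalanceStages())
        expect_length(rep@ordered_witness, 4L)
        ## consecutive witness stages are causally entailed
        w <- rep@ordered_witness
        for (i in 1:3) {
            expect_true(hasEdge(fixtureGraph, w[i], "has_result", w[i + 1L]),
                        label = paste(course, i))
        }
    }
    ## witness-existence implies all four stages present (checked above);
    ## reports are deterministic
    r1 <- checkCoursePattern(fixtureGraph, "HOIP:0060195")
    r2 <- checkCoursePattern(fixtureGraph, "HOIP:0060195")
    expect_identical(r1@ordered_witness, r2@ordered_witness)
})

test_that("a truncated course reports its missing stage and finds no witness", {
    doc <- senescenceOntology()
    ## untag the acute imbalance node
    doc@terms$stage[doc@terms$id == "HOIP:0099011"] <- NA_character_
    g <- materialize(doc)
    rep <- checkCoursePattern(g, "HOIP:0060196")
    expect_identical(rep@missing, "imbalance")
    expect_length(rep@ordered_witness, 0L)
    ## a course with no tagged members misses all four stages
    ax <- exAx("K:1", "has_part", "P:1")
    plain <- materialize(quickDoc(ax, kinds = c("K:1" = "course")))
    rep0 <- checkCoursePattern(plain, "K:1")
    expect_setequal(rep0@missing, imbalanceStages())
    expect_length(rep0@ordered_witness, 0L)
    ## JSON export carries the full report
    js <- jsonlite::fromJSON(patternToJSON(rep))
    expect_identical(js$missing, "imbalance")
})

test_that("stage tags persist through serialization round-trips", {
    for (fmt in c("turtle", "rdfxml")) {
        back <- readOntology(writeOntology(fixtureDoc, format = fmt),
                             format = fmt, fromText = TRUE)$document
        expect_identical(stageTags(back), stageTags(fixtureDoc), label = fmt)
    }
})
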