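test_that("course membership inherits, specializes and adds across the hierarchy", {
    m <- courseMembers(fixtureGraph, "HOIP:0060195")
    ## sustained senescence replaces plain cellular senescence
    expect_false("HOIP:0060129" %in% m$id)
    spec <- m[m$origin == "specialized", ]
    expect_identical(spec$id, "HOIP:0060240")
    expect_identical(spec$replaces, "HOIP:0060129")
    ## added processes are direct, inherited ones flagged as such
    expect_identical(m$origin[m$id == "HOIP:0060308"], "direct")
    expect_identical(m$origin[m$id == "HOIP:0060113"], "direct")
    expect_identical(m$origin[m$id == "HOIP:0060110"], "inherited")
    ## the acquired chronic processes
    expect_true(all(c("HOIP:0060431", "HOIP:0060294", "HOIP:0060321",
                      "HOIP:0060162") %in% m$id))
    ## inheritance monotonicity: a subcourse keeps each supercourse member
    ## or a specialization of it
    mSub <- courseMembers(fixtureGraph, "HOIP:0060423")
    subsump <- subsumptions(fixtureGraph)
    for (p in m$id) {
        covered <- p %in% mSub$id ||
            any(subsump$sub %in% mSub$id & subsump$super == p)
        expect_true(covered, label = p)
    }
})

test_that("membership requires a course class and tolerates empty courses", {
    expect_error(courseMembers(fixtureGraph, "HOIP:0060102"), "not a course")
    doc <- makeOntologyDocument(
        terms = data.frame(id = "K:1", entity_kind = "course"))
    expect_identical(nrow(courseMembers(materialize(doc), "K:1")), 0L)
})

test_that("course-scoped causes separate the per-course p21 chains", {
    adult <- causesOf(fixtureGraph, "HOIP:0060325", course = "HOIP:0060315")
    expect_true(all(c("HOIP:0060110", "HOIP:0060055", "HOIP:0099003") %in% adult))
    expect_false(any(c("HOIP:0060269", "HOIP:0060290") %in% adult))
    emb <- causesOf(fixtureGraph, "HOIP:0060325", course = "HOIP:0060267")
    expect_true(all(c("HOIP:0060269", "HOIP:0060290", "HOIP:0099005") %in% emb))
    expect_false(any(c("HOIP:0060110", "HOIP:0060055") %in% emb))
    ## scope soundness: every scoped cause is itself a course member
    members <- courseMembers(fixtureGraph, "HOIP:0060315")$id
    expect_true(all(adult %in% members))
    ## a process outside the course is a scope error
    expect_error(causesOf(fixtureGraph, "HOIP:0060427", course = "HOIP:0060315"),
                 "not a member")
    ## a source node has no causes
    expect_identical(causesOf(fixtureGraph, "HOIP:0060431"), character(0))
})

test_that("results mirror causes through the inverse relation (duality)", {
    res <- resultsOf(fixtureGraph, "HOIP:0060102")
    expect_true(all(c("HOIP:0060113", "HOIP:0060112", "HOIP:0060182") %in% res))
    expect_identical(resultsOf(fixtureGraph, "HOIP:0099008"), character(0)) # sink
    ## duality on a random fixture: x in causes(y) <=> y in results(x)
    r <- randomOntology(nClasses = 15, seed = 13)
    g <- materialize(r$document)
    ids <- ontoTerms(r$document)$id
    for (y in ids) {
        for (x in causesOf(g, y)) {
            expect_true(y %in% resultsOf(g, x), label = paste(x, y))
        }
    }
    for (x in ids) {
        for (y in resultsOf(g, x)) {
            expect_true(x %in% causesOf(g, y), label = paste(x, y))
        }
    }
})

test_that("causal paths enumerate asserted chains, not inferred shortcuts", {
    p <- causalPaths(fixtureGraph, "HOIP:0060431", "HOIP:0060427", 6)
    expect_true(any(vapply(p, function(x) identical(x,
        c("HOIP:0060431", "HOIP:0060453", "HOIP:0060455", "HOIP:0060432",
          "HOIP:0060427")), logical(1))))
    ## each consecutive pair is an asserted edge; src/dst are entailed
    ax <- ontoAxioms(fixtureDoc)
    asserted <- paste(ax$subject, ax$object)[ax$kind == "existential" &
                                                 ax$relation == "has_result"]
    for (path in p) {
        for (i in seq_len(length(path) - 1L)) {
            expect_true(paste(path[i], path[i + 1L]) %in% asserted)
        }
        expect_true(hasEdge(fixtureGraph, path[1L], "has_result",
                            path[length(path)]))
    }
    ## trivial and unreachable cases
    expect_identical(causalPaths(fixtureGraph, "HOIP:0060431", "HOIP:0060431", 3),
                     list("HOIP:0060431"))
    expect_identical(causalPaths(fixtureGraph, "HOIP:0060427", "HOIP:0060431", 6),
                     list())
})

test_that("path enumeration matches a brute-force DFS on random DAGs", {
    dfsPaths <- function(edges, src, dst, maxLen) {
        out <- list()
        recur <- function(node, path) {
            if (node == dst && length(path) > 1L) {
                out[[length(out) + 1L]] <<- path
                return()
            }
            if (length(path) > maxLen) return()
            nxt <- sort(edges$object[edges$subject == node])
            for (v in setdiff(nxt, path)) recur(v, c(path, v))
        }
        if (src == dst) return(list(src))
        recur(src, src)
        out[order(vapply(out, paste, character(1), collapse = "\r"))]
    }
    for (s in c(2L, 8L)) {
        r <- randomOntology(nClasses = 12, seed = s, chainDensity = 0)
        g <- materialize(r$document)
        ax <- ontoAxioms(r$document)
        ## view asserted causal edges in result orientation
        ex <- ax[ax$kind == "existential" & ax$relation %in%
                     c("has_result", "has_cause"), ]
        flip <- ex$relation == "has_cause"
        edges <- data.frame(subject = ifelse(flip, ex$object, ex$subject),
                            object = ifelse(flip, ex$subject, ex$object),
                            stringsAsFactors = FALSE)
        ids <- ontoTerms(r$document)$id
        for (pair in list(c(1L, 10L), c(2L, 12L))) {
            src <- ids[pair[1L]]; dst <- ids[pair[2L]]
            mine <- causalPaths(g, src, dst, 6)
            ## engine paths use asserted result-orientation edges only
            expect_identical(mine, dfsPaths(edges, src, dst, 6),
                             label = paste("seed", s, src, dst))
        }
    }
})

test_that("cross-course inference finds per-course effects of IL-8 signaling variants", {
    cc <- crossCourseResults(fixtureGraph, "HOIP:0041903")
    expect_true("HOIP:0060113" %in% cc[["HOIP:0060195"]])
    expect_true("HOIP:0041811" %in% cc[["HOIP:0099101"]])
    expect_true("HOIP:0039281" %in% cc[["HOIP:0099102"]])
    ## a process absent from every course yields an empty map
    expect_length(crossCourseResults(fixtureGraph, "HOIP:0099008"), 0L)
    ## set-algebra oracle: each course entry equals the union of the
    ## variants' unrestricted results intersected with course membership
    subsump <- subsumptions(fixtureGraph)
    variants <- c("HOIP:0041903",
                  subsump$sub[subsump$super == "HOIP:0041903"])
    for (course in names(cc)) {
        m <- courseMembers(fixtureGraph, course)$id
        expected <- sort(intersect(
            unique(unlist(lapply(intersect(variants, m), function(v)
                resultsOf(fixtureGraph, v)))), m))
        expect_identical(cc[[course]], expected, label = course)
    }
})

test_that("common generalized processes surface shared innate-immunity superclasses", {
    cg <- commonGeneralizedProcesses(fixtureGraph, "HOIP:0060195", "HOIP:0099101")
    expect_true(nrow(cg) > 0L)
    ## IL-8 variants meet at the generic IL-8 signaling class
    hit <- cg[cg$memberA == "HOIP:0060640" & cg$memberB == "HOIP:0099110", ]
    expect_identical(hit$superclass, "HOIP:0041903")
    ## inflammation processes meet at the inflammatory-response class
    expect_true(any(cg$superclass == "GO:0006954"))
    expect_true(any(cg$superclass == "GO:0045087"))
    ## excluded hub classes never appear
    expect_false(any(cg$superclass %in% c("GO:0008150", "HOIP:0099001")))
    ## disjoint hierarchies share nothing
    ax <- rbind(exAx("K:1", "has_part", "P:1"), exAx("K:2", "has_part", "P:2"))
    doc <- quickDoc(ax, kinds = c("K:1" = "course", "K:2" = "course"))
    expect_identical(nrow(commonGeneralizedProcesses(materialize(doc),
                                                     "K:1", "K:2")), 0L)
    ## brute-force ancestor-set oracle on the fixture pair
    anc <- function(x) c(x, subsumptions(fixtureGraph)$super[
        subsumptions(fixtureGraph)$sub == x])
    mA <- courseMembers(fixtureGraph, "HOIP:0060195")$id
    mB <- courseMembers(fixtureGraph, "HOIP:0099101")$id
    excl <- c("HOIP:0099001", "GO:0008150")
    expectPairs <- 0L
    for (a in mA) for (b in mB) {
        if (a != b && length(setdiff(intersect(anc(a), anc(b)), excl)))
            expectPairs <- expectPairs + 1L
    }
    expect_identical(nrow(cg), expectPairs)
})

test_that("generalized causal networks merge courses at the abstraction level", {
    abstraction <- c("HOIP:0060640" = "HOIP:0041903",
                     "HOIP:0099110" = "HOIP:0041903",
                     "HOIP:0099112" = "HOIP:0099116",
                     "HOIP:0099113" = "HOIP:0099116")
    net <- generalizedCausalNetwork(fixtureGraph,
                                    c("HOIP:0060195", "HOIP:0099101"),
                                    abstraction)
    e <- graphEdges(net)
    key <- paste(e$subject, e$object)
    ## IL-8 signaling -> NET formation/NETosis -> thrombus formation
    expect_true("HOIP:0041903 HOIP:0099116" %in% key)
    expect_true("HOIP:0099116 HOIP:0041811" %in% key)
    ## quotient-graph oracle: an edge exists iff some mapped member pair
    ## carries an entailed causal edge
    members <- union(courseMembers(fixtureGraph, "HOIP:0060195")$id,
                     courseMembers(fixtureGraph, "HOIP:0099101")$id)
    mapTo <- function(x) if (x %in% names(abstraction)) abstraction[[x]] else x
    closure <- inferredEdges(fixtureGraph)
    causal <- closure[closure$relation == "has_result" &
                          closure$subject %in% members &
                          closure$object %in% members, ]
    expected <- unique(data.frame(
        subject = vapply(causal$subject, mapTo, character(1), USE.NAMES = FALSE),
        object = vapply(causal$object, mapTo, character(1), USE.NAMES = FALSE),
        stringsAsFactors = FALSE))
    expected <- expected[expected$subject != expected$object, ]
    expect_setequal(key, paste(expected$subject, expected$object))
    ## a bad abstraction target is a mapping error
    expect_error(generalizedCausalNetwork(fixtureGraph, "HOIP:0060195",
                                          c("HOIP:0060640" = "HOIP:0060113")),
                 "not an ancestor")
    ## single course under the identity abstraction keeps its own nodes
    solo <- generalizedCausalNetwork(fixtureGraph, "HOIP:0060423")
    expect_true(all(courseMembers(fixtureGraph, "HOIP:0060423")$id %in%
                        graphNodes(solo)$id))
})
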