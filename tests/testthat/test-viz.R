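test_that("node styling follows the legend: squares for molecules, red for human, grey for negations", {
    s <- styleFor(fixtureDoc, "PR:P20700")       # human LMNB1
    expect_identical(s$shape, "square")
    expect_identical(s$color, defaultPalette()$human_material)
    s <- styleFor(fixtureDoc, "CHEBI:6801")      # non-human molecule
    expect_identical(s$shape, "square")
    expect_identical(s$color, defaultPalette()$material_entity)
    s <- styleFor(fixtureDoc, "HOIP:0099016")    # "no SASP secretion"
    expect_identical(s$shape, "circle")
    expect_identical(s$color, defaultPalette()$negated)
    ## arbitrary process: default circle; unknown id: fallback style
    expect_identical(styleFor(fixtureDoc, "HOIP:0060102")$shape, "circle")
    expect_identical(styleFor(fixtureDoc, "XX:000001")$color,
                     defaultPalette()$other)
    ## palette overrides apply
    s <- styleFor(fixtureDoc, "HOIP:0099016",
                  palette = utils::modifyList(defaultPalette(),
                                              list(negated = "#123456")))
    expect_identical(s$color, "#123456")
    ## edge styles: is-a dotted without arrow, causal solid with arrow
    expect_identical(edgeStyleFor("is_a"), list(line = "dotted", arrow = FALSE))
    expect_identical(edgeStyleFor("has_result"),
                     list(line = "solid", arrow = TRUE))
})

test_that("SIF export is one sorted line per edge", {
    cg <- courseGraph(fixtureGraph, "HOIP:0060195")
    sif <- toSIF(cg)
    lines <- strsplit(sif, "\n", fixed = TRUE)[[1]]
    expect_identical(length(lines), nrow(graphEdges(cg)))
    expect_true("HOIP:0060190\thas_result\tHOIP:0060172" %in% lines)
    expect_identical(lines, sort(lines))
    ## deterministic byte-for-byte
    expect_identical(sif, toSIF(courseGraph(fixtureGraph, "HOIP:0060195")))
    ## single-edge and empty graphs
    g1 <- materialize(quickDoc(exAx("A:1", "has_result", "A:2")))
    cg1 <- generalizedCausalNetwork(g1, character(0))
    expect_identical(toSIF(cg1), "")
})

test_that("GraphML embeds attributes and styles and agrees with the other exports on counts", {
    cg <- courseGraph(fixtureGraph, "HOIP:0060418", includeSupercourses = TRUE)
    gml <- toGraphML(cg)
    x <- xml2::read_xml(gml)
    nNodes <- length(xml2::xml_find_all(x, "//*[local-name()='node']"))
    nEdges <- length(xml2::xml_find_all(x, "//*[local-name()='edge']"))
    expect_identical(nNodes, nrow(graphNodes(cg)))
    expect_identical(nEdges, nrow(graphEdges(cg)))
    ## grey negation node and dotted is-a edge styles are present
    expect_match(gml, defaultPalette()$negated, fixed = TRUE)
    expect_match(gml, ">dotted<")
    ## counts agree across SIF / GraphML / CX
    sifLines <- strsplit(toSIF(cg), "\n")[[1]]
    cx <- readCX(toCX(cg))
    expect_identical(length(sifLines), nEdges)
    expect_identical(nrow(cx$nodes), nNodes)
    expect_identical(nrow(cx$edges), nEdges)
})

test_that("CX export parses as JSON and re-imports losslessly", {
    cg <- courseGraph(fixtureGraph, "HOIP:0060418", includeSupercourses = TRUE)
    cx <- toCX(cg)
    back <- readCX(cx)
    expect_setequal(back$nodes$curie, graphNodes(cg)$id)
    e <- graphEdges(cg)
    expect_setequal(paste(back$edges$source, back$edges$relation, back$edges$target),
                    paste(e$subject, e$relation, e$object))
    ## styling survives: grey fill on the negation nodes, dotted is-a edges
    grey <- back$nodeAttributes[back$nodeAttributes$n == "color" &
                                    back$nodeAttributes$v ==
                                    defaultPalette()$negated, ]
    greyIds <- back$nodes$curie[match(grey$po, back$nodes$id)]
    expect_true(all(c("HOIP:0099015", "HOIP:0099016") %in% greyIds))
    dotted <- back$edgeAttributes[back$edgeAttributes$n == "line" &
                                      back$edgeAttributes$v == "dotted", ]
    expect_identical(nrow(dotted), sum(e$relation == "is_a"))
    ## empty graph still yields valid CX
    empty <- generalizedCausalNetwork(fixtureGraph, character(0))
    expect_identical(nrow(readCX(toCX(empty))$nodes), 0L)
})

test_that("the node table carries definitions, cross-references and public URIs", {
    cg <- courseGraph(fixtureGraph, "HOIP:0060195")
    nt <- nodeTable(cg)
    expect_identical(nrow(nt), nrow(graphNodes(cg)))
    sasp <- nt[nt$id == "HOIP:0060102", ]
    expect_match(sasp$uri, "/HOIP0060102$")
    expect_match(sasp$definition, "senescence-associated")
    ## PubMed link derived from the PMID cross-reference
    adult <- nodeTable(courseGraph(fixtureGraph, "HOIP:0060315"))
    chk1 <- adult[adult$id == "HOIP:0060144", ]
    expect_identical(chk1$pubmed, "https://pubmed.ncbi.nlm.nih.gov/33328614/")
    ## deterministic row order, TSV writing
    path <- tempfile(fileext = ".tsv")
    nodeTable(cg, path = path)
    expect_identical(nrow(utils::read.delim(path)), nrow(nt))
})

test_that("the materialized closure exports as a triple table", {
    path <- tempfile(fileext = ".tsv")
    tt <- tripleTable(fixtureGraph, path = path)
    expect_identical(sort(unique(tt$status)), c("asserted", "inferred"))
    back <- utils::read.delim(path, stringsAsFactors = FALSE)
    expect_identical(nrow(back), nrow(tt))
})
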