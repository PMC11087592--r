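## Export of course graphs with the visualization conventions used for
## senescence course networks: processes as circles, material entities as
## squares, human molecules red, negation-marked ("no X") processes grey,
## is-a edges dotted, causal/part edges solid with arrows.

#' Default node-style palette
#'
#' Colors per entity kind; exact values are conventions, overridable per
#' call.  Human-taxon molecules get \code{human_material}; negation-marked
#' processes get \code{negated}.
#' @return named list of fill colors.
#' @export
defaultPalette <- function() {
    list(process = "#FFFFFF", course = "#D3D3D3",
         material_entity = "#FFA500", human_material = "#FF0000",
         role = "#90EE90", phenotype = "#008000", symptom = "#4169E1",
         disease = "#DC143C", anatomical_entity = "#F5DEB3",
         other = "#EEEEEE", negated = "#BEBEBE")
}

isHumanTaxon <- function(taxon) {
    !is.na(taxon) & (grepl("9606", taxon) | grepl("human", taxon, ignore.case = TRUE) |
                         grepl("Homo sapiens", taxon, ignore.case = TRUE))
}

#' Node style for a term
#'
#' Processes map to circles and material entities to squares; human
#' molecules are filled red, negation-marked processes grey; other kinds
#' take their palette color.  Unknown kinds fall back to a default style.
#'
#' @param doc an \linkS4class{OntologyDocument} (or a
#'   \linkS4class{CourseGraph}, whose term table is used).
#' @param id term CURIE.
#' @param palette color overrides, see \code{\link{defaultPalette}}.
#' @return list with \code{shape} (circle/square), \code{color}, \code{border}.
#' @export
styleFor <- function(doc, id, palette = defaultPalette()) {
    tt <- if (methods::is(doc, "CourseGraph")) doc@termInfo else doc@terms
    id <- normalizeCurie(id)
    i <- match(id, tt$id)
    if (is.na(i)) {
        return(list(shape = "circle", color = palette$other, border = "#000000"))
    }
    kind <- tt$entity_kind[i]
    shape <- if (kind == "material_entity") "square" else "circle"
    color <- if (isTRUE(tt$negated[i])) {
        palette$negated
    } else if (kind == "material_entity" && isHumanTaxon(tt$taxon[i])) {
        palette$human_material
    } else if (!is.null(palette[[kind]])) {
        palette[[kind]]
    } else {
        palette$other
    }
    list(shape = shape, color = color, border = "#000000")
}

#' Edge style for a relation
#'
#' \code{is_a} display edges are dotted without an arrow; all causal,
#' part-whole and attachment edges are solid and arrowed.
#'
#' @param relation relation id.
#' @return list with \code{line} (solid/dotted) and \code{arrow} (logical).
#' @export
edgeStyleFor <- function(relation) {
    if (relation == "is_a") list(line = "dotted", arrow = FALSE)
    else list(line = "solid", arrow = TRUE)
}

nodeStyleTable <- function(graph, palette = defaultPalette()) {
    ids <- graph@nodes$id
    sty <- lapply(ids, function(i) styleFor(graph, i, palette))
    data.frame(id = ids,
               shape = vapply(sty, `[[`, character(1), "shape"),
               color = vapply(sty, `[[`, character(1), "color"),
               stringsAsFactors = FALSE)
}

#' Export a course graph as SIF
#'
#' One line per edge, \code{source<TAB>relation<TAB>target}, sorted.
#' @param graph a \linkS4class{CourseGraph}.
#' @param path optional output file.
#' @return SIF text, invisibly if written to a file.
#' @export
toSIF <- function(graph, path = NULL) {
    e <- graph@edges
    lines <- paste(e$subject, e$relation, e$object, sep = "\t")
    lines <- sort(lines)
    text <- paste0(paste(lines, collapse = "\n"),
                   if (length(lines)) "\n" else "")
    if (!is.null(path)) { writeLines(text, path, sep = ""); return(invisible(text)) }
    text
}

pubmedLink <- function(xrefs) {
    if (is.na(xrefs) || !nzchar(xrefs)) return(NA_character_)
    parts <- strsplit(xrefs, ";", fixed = TRUE)[[1]]
    pm <- parts[grepl("^PMID:", parts)]
    if (length(pm) == 0L) return(NA_character_)
    paste0("https://pubmed.ncbi.nlm.nih.gov/", sub("^PMID:", "", pm[1L]), "/")
}

#' Node attribute table of a course graph
#'
#' One row per node: id, label, kind, definition, cross-references,
#' public URI (the BioPortal pattern for HOIP classes) and a PubMed link
#' when a PMID cross-reference is present.
#'
#' @param graph a \linkS4class{CourseGraph}.
#' @param path optional output TSV file.
#' @return data.frame, sorted by id; written as TSV when \code{path} given.
#' @export
nodeTable <- function(graph, path = NULL) {
    tt <- graph@termInfo
    ids <- sort(graph@nodes$id)
    i <- match(ids, tt$id)
    out <- data.frame(id = ids,
                      label = tt$label[i],
                      entity_kind = graph@nodes$entity_kind[match(ids, graph@nodes$id)],
                      definition = tt$definition[i],
                      xrefs = tt$xrefs[i],
                      uri = curieToURI(ids),
                      pubmed = vapply(tt$xrefs[i], pubmedLink, character(1),
                                      USE.NAMES = FALSE),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    if (!is.null(path)) {
        utils::write.table(out, path, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "")
    }
    out
}

#' Export a course graph as GraphML
#'
#' Embeds per-node attributes (label, entity kind, definition, URI,
#' PubMed link, shape, fill color) and per-edge attributes (relation,
#' status, line style, arrow flag).
#'
#' @param graph a \linkS4class{CourseGraph}.
#' @param path optional output file.
#' @param palette color overrides.
#' @return GraphML text, invisibly if written to a file.
#' @export
toGraphML <- function(graph, path = NULL, palette = defaultPalette()) {
    nt <- nodeTable(graph)
    sty <- nodeStyleTable(graph, palette)
    e <- graph@edges
    esc <- xmlEscape
    keys <- c(
        "<key id=\"label\" for=\"node\" attr.name=\"label\" attr.type=\"string\"/>",
        "<key id=\"kind\" for=\"node\" attr.name=\"entity_kind\" attr.type=\"string\"/>",
        "<key id=\"definition\" for=\"node\" attr.name=\"definition\" attr.type=\"string\"/>",
        "<key id=\"uri\" for=\"node\" attr.name=\"uri\" attr.type=\"string\"/>",
        "<key id=\"pubmed\" for=\"node\" attr.name=\"pubmed\" attr.type=\"string\"/>",
        "<key id=\"shape\" for=\"node\" attr.name=\"shape\" attr.type=\"string\"/>",
        "<key id=\"color\" for=\"node\" attr.name=\"color\" attr.type=\"string\"/>",
        "<key id=\"relation\" for=\"edge\" attr.name=\"relation\" attr.type=\"string\"/>",
        "<key id=\"status\" for=\"edge\" attr.name=\"status\" attr.type=\"string\"/>",
        "<key id=\"line\" for=\"edge\" attr.name=\"line\" attr.type=\"string\"/>",
        "<key id=\"arrow\" for=\"edge\" attr.name=\"arrow\" attr.type=\"boolean\"/>")
    nodeXml <- vapply(seq_len(nrow(nt)), function(i) {
        dat <- function(k, v) {
            if (is.na(v)) "" else paste0("      <data key=\"", k, "\">",
                                         esc(v), "</data>\n")
        }
        paste0("    <node id=\"", esc(nt$id[i]), "\">\n",
               dat("label", nt$label[i]), dat("kind", nt$entity_kind[i]),
               dat("definition", nt$definition[i]), dat("uri", nt$uri[i]),
               dat("pubmed", nt$pubmed[i]),
               dat("shape", sty$shape[match(nt$id[i], sty$id)]),
               dat("color", sty$color[match(nt$id[i], sty$id)]),
               "    </node>")
    }, character(1))
    edgeXml <- vapply(seq_len(nrow(e)), function(i) {
        es <- edgeStyleFor(e$relation[i])
        paste0("    <edge source=\"", esc(e$subject[i]), "\" target=\"",
               esc(e$object[i]), "\">\n",
               "      <data key=\"relation\">", esc(e$relation[i]), "</data>\n",
               "      <data key=\"status\">", esc(e$status[i]), "</data>\n",
               "      <data key=\"line\">", es$line, "</data>\n",
               "      <data key=\"arrow\">", tolower(es$arrow), "</data>\n",
               "    </edge>")
    }, character(1))
    text <- paste0(
        "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
        "<graphml xmlns=\"http://graphml.graphdrawing.org/xmlns\">\n",
        paste0("  ", keys, collapse = "\n"), "\n",
        "  <graph id=\"", esc(graph@course_id), "\" edgedefault=\"directed\">\n",
        paste(nodeXml, collapse = "\n"),
        if (nrow(nt) && nrow(e)) "\n" else "",
        paste(edgeXml, collapse = "\n"),
        if (nrow(e)) "\n" else "",
        "  </graph>\n</graphml>\n")
    if (!is.null(path)) { writeLines(text, path, sep = ""); return(invisible(text)) }
    text
}

#' Export a course graph as CX (network exchange JSON)
#'
#' Emits the aspects consumed by NDEx-compatible tools: \code{nodes},
#' \code{edges}, \code{nodeAttributes} (label is the \code{name}
#' attribute; entity kind, definition, URI, PubMed link, shape, color) and
#' \code{edgeAttributes} (line style, arrow, status), plus
#' \code{metaData} and a closing \code{status} aspect.
#'
#' @param graph a \linkS4class{CourseGraph}.
#' @param path optional output file.
#' @param palette color overrides.
#' @return CX JSON text, invisibly if written to a file.
#' @export
toCX <- function(graph, path = NULL, palette = defaultPalette()) {
    nt <- nodeTable(graph)
    sty <- nodeStyleTable(graph, palette)
    e <- graph@edges
    nodeIds <- stats::setNames(seq_len(nrow(nt)) - 1L, nt$id)
    nodes <- lapply(nt$id, function(id) {
        list(`@id` = unname(nodeIds[id]),
             n = if (is.na(nt$label[match(id, nt$id)])) id
                 else nt$label[match(id, nt$id)],
             r = id)
    })
    edges <- lapply(seq_len(nrow(e)), function(i) {
        list(`@id` = nrow(nt) + i - 1L,
             s = unname(nodeIds[e$subject[i]]),
             t = unname(nodeIds[e$object[i]]),
             i = e$relation[i])
    })
    nattr <- list()
    addNA <- function(po, n, v) {
        if (!is.na(v)) nattr[[length(nattr) + 1L]] <<-
            list(po = unname(nodeIds[po]), n = n, v = v)
    }
    for (id in nt$id) {
        j <- match(id, nt$id)
        addNA(id, "entity_kind", nt$entity_kind[j])
        addNA(id, "definition", nt$definition[j])
        addNA(id, "uri", nt$uri[j])
        addNA(id, "pubmed", nt$pubmed[j])
        addNA(id, "shape", sty$shape[match(id, sty$id)])
        addNA(id, "color", sty$color[match(id, sty$id)])
    }
    eattr <- list()
    for (i in seq_len(nrow(e))) {
        es <- edgeStyleFor(e$relation[i])
        eid <- nrow(nt) + i - 1L
        eattr[[length(eattr) + 1L]] <- list(po = eid, n = "line", v = es$line)
        eattr[[length(eattr) + 1L]] <- list(po = eid, n = "arrow",
                                            v = tolower(es$arrow))
        eattr[[length(eattr) + 1L]] <- list(po = eid, n = "status",
                                            v = e$status[i])
    }
    meta <- lapply(c("nodes", "edges", "nodeAttributes", "edgeAttributes"),
                   function(n) list(name = n, version = "1.0"))
    cx <- list(
        list(numberVerification = list(list(longNumber = 281474976710655))),
        list(metaData = meta),
        list(nodes = nodes),
        list(edges = edges),
        list(nodeAttributes = nattr),
        list(edgeAttributes = eattr),
        list(status = list(list(error = "", success = TRUE))))
    text <- as.character(jsonlite::toJSON(cx, auto_unbox = TRUE))
    if (!is.null(path)) { writeLines(text, path); return(invisible(text)) }
    text
}

#' Re-import a CX document
#'
#' Parses CX JSON (as written by \code{\link{toCX}}) back into node and
#' edge tables, for lossless round-trip checks.
#'
#' @param text CX JSON text or a path to a file.
#' @return list with data.frames \code{nodes} (\code{id}, \code{curie},
#'   \code{label}), \code{edges} (\code{source}, \code{target},
#'   \code{relation}), \code{nodeAttributes}, \code{edgeAttributes}.
#' @export
readCX <- function(text) {
    if (length(text) == 1L && file.exists(text)) {
        text <- paste(readLines(text, warn = FALSE), collapse = "\n")
    }
    cx <- jsonlite::fromJSON(text, simplifyVector = FALSE)
    aspect <- function(name) {
        for (a in cx) if (!is.null(a[[name]])) return(a[[name]])
        list()
    }
    ns <- aspect("nodes")
    nodes <- data.frame(
        id = vapply(ns, function(x) as.integer(x$`@id`), integer(1)),
        curie = vapply(ns, function(x) as.character(x$r), character(1)),
        label = vapply(ns, function(x) as.character(x$n), character(1)),
        stringsAsFactors = FALSE)
    es <- aspect("edges")
    idmap <- stats::setNames(nodes$curie, nodes$id)
    edges <- data.frame(
        source = vapply(es, function(x) unname(idmap[as.character(x$s)]), character(1)),
        target = vapply(es, function(x) unname(idmap[as.character(x$t)]), character(1)),
        relation = vapply(es, function(x) as.character(x$i), character(1)),
        stringsAsFactors = FALSE)
    na <- aspect("nodeAttributes")
    nodeAttributes <- data.frame(
        po = vapply(na, function(x) as.integer(x$po), integer(1)),
        n = vapply(na, function(x) as.character(x$n), character(1)),
        v = vapply(na, function(x) as.character(x$v), character(1)),
        stringsAsFactors = FALSE)
    ea <- aspect("edgeAttributes")
    edgeAttributes <- data.frame(
        po = vapply(ea, function(x) as.integer(x$po), integer(1)),
        n = vapply(ea, function(x) as.character(x$n), character(1)),
        v = vapply(ea, function(x) as.character(x$v), character(1)),
        stringsAsFactors = FALSE)
    list(nodes = nodes, edges = edges, nodeAttributes = nodeAttributes,
         edgeAttributes = edgeAttributes)
}

#' Export an inferred graph as a triple table (TSV)
#'
#' @param graph an \linkS4class{InferredGraph}.
#' @param path optional output TSV file.
#' @return data.frame (\code{subject}, \code{relation}, \code{object},
#'   \code{status}).
#' @export
tripleTable <- function(graph, path = NULL) {
    e <- graph@edges[, c("subject", "relation", "object", "status")]
    rownames(e) <- NULL
    if (!is.null(path)) {
        utils::write.table(e, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    e
}
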