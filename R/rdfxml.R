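## RDF/XML reader/writer over the same triple table as the Turtle side.

xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    x <- gsub(">", "&gt;", x, fixed = TRUE)
    x <- gsub("\"", "&quot;", x, fixed = TRUE)
    x
}

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"

## serialize: blank nodes are nested where they occur as objects
## (restrictions); rdf lists are written with rdf:first/rdf:rest nodes.
rdfxmlSerialize <- function(triples, prefixes) {
    qname <- function(iri) {
        for (p in names(prefixes)) {
            base <- prefixes[[p]]
            if (startsWith(iri, base)) {
                loc <- substr(iri, nchar(base) + 1L, nchar(iri))
                if (grepl("^[A-Za-z_][A-Za-z0-9_.-]*$", loc)) {
                    return(paste0(p, ":", loc))
                }
            }
        }
        NA_character_
    }
    bnodeRows <- function(b) triples[triples$s == b, , drop = FALSE]
    topSubjects <- setdiff(unique(triples$s),
                           triples$o[triples$o_iri & startsWith(triples$o, "_:")])

    renderNode <- function(s, indent) {
        rows <- triples[triples$s == s, , drop = FALSE]
        pad <- strrep(" ", indent)
        typeIri <- rows$o[rows$p == paste0(RDF_NS, "type") & rows$o_iri]
        elem <- "rdf:Description"
        consumedType <- character(0)
        if (length(typeIri)) {
            q <- qname(typeIri[1L])
            if (!is.na(q)) { elem <- q; consumedType <- typeIri[1L] }
        }
        about <- if (startsWith(s, "_:")) {
            paste0(" rdf:nodeID=\"", sub("^_:", "", s), "\"")
        } else {
            paste0(" rdf:about=\"", xmlEscape(s), "\"")
        }
        out <- paste0(pad, "<", elem, about, ">")
        for (i in seq_len(nrow(rows))) {
            p <- rows$p[i]; o <- rows$o[i]; oi <- rows$o_iri[i]
            if (p == paste0(RDF_NS, "type") && oi && o %in% consumedType) {
                consumedType <- setdiff(consumedType, o)
                next
            }
            pq <- qname(p)
            if (is.na(pq)) stop("cannot serialize predicate outside declared namespaces: ", p)
            if (!oi) {
                out <- c(out, paste0(pad, "  <", pq, ">", xmlEscape(o), "</", pq, ">"))
            } else if (startsWith(o, "_:")) {
                out <- c(out, paste0(pad, "  <", pq, ">"),
                         renderNode(o, indent + 4L),
                         paste0(pad, "  </", pq, ">"))
            } else {
                out <- c(out, paste0(pad, "  <", pq, " rdf:resource=\"",
                                     xmlEscape(o), "\"/>"))
            }
        }
        c(out, paste0(pad, "</", elem, ">"))
    }

    decls <- vapply(names(prefixes), function(p)
        paste0("xmlns:", p, "=\"", prefixes[[p]], "\""), character(1))
    body <- unlist(lapply(topSubjects, renderNode, indent = 2L))
    paste0("<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n<rdf:RDF\n  ",
           paste(decls, collapse = "\n  "), ">\n",
           paste(body, collapse = "\n"),
           "\n</rdf:RDF>\n")
}

rdfxmlParse <- function(text) {
    docx <- xml2::read_xml(text)
    nsmap <- xml2::xml_ns(docx)
    expand <- function(prefixed) {
        i <- regexpr(":", prefixed, fixed = TRUE)
        if (i < 0) stop("RDF/XML parse error: unprefixed element '", prefixed, "'")
        pre <- substr(prefixed, 1L, i - 1L)
        loc <- substr(prefixed, i + 1L, nchar(prefixed))
        base <- nsmap[[pre]]
        if (is.null(base)) stop("RDF/XML parse error: unknown prefix '", pre, "'")
        paste0(base, loc)
    }
    bcount <- 0L
    triples <- list()
    emit <- function(s, p, o, o_iri) {
        triples[[length(triples) + 1L]] <<- list(s = s, p = p, o = o, o_iri = o_iri)
    }
    newBnode <- function() { bcount <<- bcount + 1L; paste0("_:b", bcount) }

    nodeSubject <- function(node) {
        about <- xml2::xml_attr(node, "about")
        nid <- xml2::xml_attr(node, "nodeID")
        if (!is.na(about)) about
        else if (!is.na(nid)) paste0("_:x", nid)
        else newBnode()
    }

    parseNodeElement <- function(node) {
        s <- nodeSubject(node)
        name <- xml2::xml_name(node, nsmap)
        if (name != "rdf:Description") {
            emit(s, paste0(RDF_NS, "type"), expand(name), TRUE)
        }
        for (child in xml2::xml_children(node)) {
            p <- expand(xml2::xml_name(child, nsmap))
            res <- xml2::xml_attr(child, "resource")
            ptype <- xml2::xml_attr(child, "parseType")
            kids <- xml2::xml_children(child)
            if (!is.na(res)) {
                emit(s, p, res, TRUE)
            } else if (identical(ptype, "Collection")) {
                items <- vapply(kids, parseNodeElement, character(1))
                if (length(items) == 0L) {
                    emit(s, p, paste0(RDF_NS, "nil"), TRUE)
                } else {
                    head <- newBnode()
                    emit(s, p, head, TRUE)
                    cur <- head
                    for (k in seq_along(items)) {
                        emit(cur, paste0(RDF_NS, "first"), items[k], TRUE)
                        if (k < length(items)) {
                            nxt <- newBnode()
                            emit(cur, paste0(RDF_NS, "rest"), nxt, TRUE)
                            cur <- nxt
                        } else {
                            emit(cur, paste0(RDF_NS, "rest"),
                                 paste0(RDF_NS, "nil"), TRUE)
                        }
                    }
                }
            } else if (length(kids)) {
                o <- parseNodeElement(kids[[1L]])
                emit(s, p, o, TRUE)
            } else {
                emit(s, p, xml2::xml_text(child), FALSE)
            }
        }
        s
    }

    for (node in xml2::xml_children(docx)) parseNodeElement(node)

    if (length(triples) == 0L) {
        return(data.frame(s = character(0), p = character(0), o = character(0),
                          o_iri = logical(0), stringsAsFactors = FALSE))
    }
    data.frame(s = vapply(triples, `[[`, character(1), "s"),
               p = vapply(triples, `[[`, character(1), "p"),
               o = vapply(triples, `[[`, character(1), "o"),
               o_iri = vapply(triples, `[[`, logical(1), "o_iri"),
               stringsAsFactors = FALSE)
}
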