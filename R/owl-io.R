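## OntologyDocument <-> triples mapping shared by the Turtle and RDF/XML
## front-ends.

OWL_NS <- "http://www.w3.org/2002/07/owl#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
HOIPV_NS <- "https://w3id.org/hoipr/vocab#"
DEFAULT_ONTOLOGY_IRI <- "https://w3id.org/hoipr/ontology"

ioPrefixes <- function() {
    c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS,
      xsd = "http://www.w3.org/2001/XMLSchema#",
      obo = "http://purl.obolibrary.org/obo/",
      oboInOwl = "http://www.geneontology.org/formats/oboInOwl#",
      dc = "http://purl.org/dc/elements/1.1/",
      hoipv = HOIPV_NS,
      HOIP = "http://purl.bioontology.org/ontology/HOIP/")
}

#' Annotation-property configuration for ontology I/O
#'
#' The annotation slots recognized as term fields (label, textual
#' definition, description, database cross-reference).  The exact IRIs an
#' ontology release uses are not fixed by any standard, so they are
#' configurable; the defaults follow common OBO practice (IAO definition,
#' oboInOwl hasDbXref, Dublin Core description).
#'
#' @param label,definition,description,xref annotation-property IRIs.
#' @return named list of IRIs.
#' @export
annotationConfig <- function(label = paste0(RDFS_NS, "label"),
                             definition = "http://purl.obolibrary.org/obo/IAO_0000115",
                             description = "http://purl.org/dc/elements/1.1/description",
                             xref = "http://www.geneontology.org/formats/oboInOwl#hasDbXref") {
    list(label = label, definition = definition, description = description,
         xref = xref)
}

relationIRI <- function(id) paste0(HOIPV_NS, id)

documentToTriples <- function(doc, config = annotationConfig()) {
    rows <- list()
    bn <- 0L
    add <- function(s, p, o, o_iri) {
        rows[[length(rows) + 1L]] <<- data.frame(s = s, p = p, o = o,
                                                 o_iri = o_iri,
                                                 stringsAsFactors = FALSE)
    }
    rdftype <- paste0(RDF_NS, "type")
    iri <- ontoMetadata(doc)$iri
    if (is.null(iri)) iri <- DEFAULT_ONTOLOGY_IRI
    add(iri, rdftype, paste0(OWL_NS, "Ontology"), TRUE)
    version <- ontoMetadata(doc)$version
    if (!is.null(version)) add(iri, paste0(OWL_NS, "versionInfo"), version, FALSE)

    rel <- doc@relations
    for (i in seq_len(nrow(rel))) {
        s <- relationIRI(rel$id[i])
        add(s, rdftype, paste0(OWL_NS, "ObjectProperty"), TRUE)
        if (isTRUE(rel$transitive[i])) {
            add(s, rdftype, paste0(OWL_NS, "TransitiveProperty"), TRUE)
        }
        if (!is.na(rel$label[i])) add(s, config$label, rel$label[i], FALSE)
        if (!is.na(rel$inverse_of[i])) {
            add(s, paste0(OWL_NS, "inverseOf"), relationIRI(rel$inverse_of[i]), TRUE)
        }
        if (!is.na(rel$chain1[i])) {
            head <- paste0("_:c", i, "a"); tail <- paste0("_:c", i, "b")
            add(s, paste0(OWL_NS, "propertyChainAxiom"), head, TRUE)
            add(head, paste0(RDF_NS, "first"), relationIRI(rel$chain1[i]), TRUE)
            add(head, paste0(RDF_NS, "rest"), tail, TRUE)
            add(tail, paste0(RDF_NS, "first"), relationIRI(rel$chain2[i]), TRUE)
            add(tail, paste0(RDF_NS, "rest"), paste0(RDF_NS, "nil"), TRUE)
        }
        if (!is.na(rel$domain_kind[i])) {
            add(s, paste0(HOIPV_NS, "domainKind"), rel$domain_kind[i], FALSE)
        }
        if (!is.na(rel$range_kind[i])) {
            add(s, paste0(HOIPV_NS, "rangeKind"), rel$range_kind[i], FALSE)
        }
    }

    tt <- doc@terms
    ax <- doc@axioms
    for (i in seq_len(nrow(tt))) {
        s <- curieToURI(tt$id[i])
        add(s, rdftype, paste0(OWL_NS, "Class"), TRUE)
        if (!is.na(tt$label[i])) add(s, config$label, tt$label[i], FALSE)
        add(s, paste0(HOIPV_NS, "entityKind"), tt$entity_kind[i], FALSE)
        if (!is.na(tt$definition[i])) add(s, config$definition, tt$definition[i], FALSE)
        if (!is.na(tt$description[i])) add(s, config$description, tt$description[i], FALSE)
        if (!is.na(tt$xrefs[i]) && nzchar(tt$xrefs[i])) {
            for (x in strsplit(tt$xrefs[i], ";", fixed = TRUE)[[1]]) {
                add(s, config$xref, x, FALSE)
            }
        }
        if (isTRUE(tt$negated[i])) add(s, paste0(HOIPV_NS, "negated"), "true", FALSE)
        if (!is.na(tt$taxon[i])) add(s, paste0(HOIPV_NS, "taxon"), tt$taxon[i], FALSE)
        if (!is.na(tt$stage[i])) add(s, paste0(HOIPV_NS, "stageTag"), tt$stage[i], FALSE)
        if (!is.na(tt$equivalent_to[i])) {
            add(s, paste0(HOIPV_NS, "equivalentNote"),
                curieToURI(tt$equivalent_to[i]), TRUE)
        }
        sub_i <- ax[ax$subject == tt$id[i], , drop = FALSE]
        for (j in seq_len(nrow(sub_i))) {
            if (sub_i$kind[j] == "subclass_of") {
                add(s, paste0(RDFS_NS, "subClassOf"), curieToURI(sub_i$object[j]), TRUE)
            } else {
                bn <- bn + 1L
                b <- paste0("_:r", bn)
                add(s, paste0(RDFS_NS, "subClassOf"), b, TRUE)
                add(b, rdftype, paste0(OWL_NS, "Restriction"), TRUE)
                add(b, paste0(OWL_NS, "onProperty"),
                    relationIRI(sub_i$relation[j]), TRUE)
                add(b, paste0(OWL_NS, "someValuesFrom"),
                    curieToURI(sub_i$object[j]), TRUE)
            }
        }
    }
    ## axioms whose subject has no term entry (dangling subjects) still
    ## serialize, so round-trips preserve them
    extra <- ax[!(ax$subject %in% tt$id), , drop = FALSE]
    for (j in seq_len(nrow(extra))) {
        s <- curieToURI(extra$subject[j])
        if (extra$kind[j] == "subclass_of") {
            add(s, paste0(RDFS_NS, "subClassOf"), curieToURI(extra$object[j]), TRUE)
        } else {
            bn <- bn + 1L
            b <- paste0("_:r", bn)
            add(s, paste0(RDFS_NS, "subClassOf"), b, TRUE)
            add(b, rdftype, paste0(OWL_NS, "Restriction"), TRUE)
            add(b, paste0(OWL_NS, "onProperty"), relationIRI(extra$relation[j]), TRUE)
            add(b, paste0(OWL_NS, "someValuesFrom"), curieToURI(extra$object[j]), TRUE)
        }
    }
    do.call(rbind, rows)
}

localName <- function(iri) sub("^.*[/#]", "", iri)

safeCurie <- function(iri) {
    tryCatch(normalizeCurie(iri), error = function(e) NA_character_)
}

triplesToDocument <- function(triples, config = annotationConfig()) {
    rdftype <- paste0(RDF_NS, "type")
    skipped <- list()
    skip <- function(construct, location) {
        skipped[[length(skipped) + 1L]] <<-
            data.frame(construct = construct, location = location,
                       stringsAsFactors = FALSE)
    }
    tf <- function(s, p) triples$o[triples$s == s & triples$p == p]
    tfi <- function(s, p) triples$o[triples$s == s & triples$p == p & triples$o_iri]
    tfl <- function(s, p) triples$o[triples$s == s & triples$p == p & !triples$o_iri]
    types <- function(s) tfi(s, rdftype)

    readList <- function(head) {
        items <- character(0)
        nil <- paste0(RDF_NS, "nil")
        while (!identical(head, nil)) {
            f <- tfi(head, paste0(RDF_NS, "first"))
            r <- tfi(head, paste0(RDF_NS, "rest"))
            if (length(f) == 0L || length(r) == 0L) return(NULL)
            items <- c(items, f[1L])
            head <- r[1L]
        }
        items
    }

    ## relations
    propSubjects <- sort(unique(triples$s[triples$p == rdftype &
        triples$o == paste0(OWL_NS, "ObjectProperty")]))
    relRows <- lapply(propSubjects, function(s) {
        id <- localName(s)
        chain <- c(NA_character_, NA_character_)
        ch <- tfi(s, paste0(OWL_NS, "propertyChainAxiom"))
        if (length(ch)) {
            items <- readList(ch[1L])
            if (is.null(items) || length(items) != 2L) {
                skip("propertyChainAxiom with other than two elements", s)
            } else {
                chain <- vapply(items, localName, character(1), USE.NAMES = FALSE)
            }
        }
        invs <- tfi(s, paste0(OWL_NS, "inverseOf"))
        lab <- tfl(s, config$label)
        dk <- tfl(s, paste0(HOIPV_NS, "domainKind"))
        rk <- tfl(s, paste0(HOIPV_NS, "rangeKind"))
        data.frame(id = id,
                   label = if (length(lab)) lab[1L] else NA_character_,
                   transitive = paste0(OWL_NS, "TransitiveProperty") %in% types(s),
                   inverse_of = if (length(invs)) localName(invs[1L]) else NA_character_,
                   chain1 = chain[1L], chain2 = chain[2L],
                   domain_kind = if (length(dk)) dk[1L] else NA_character_,
                   range_kind = if (length(rk)) rk[1L] else NA_character_,
                   stringsAsFactors = FALSE)
    })
    relations <- if (length(relRows)) do.call(rbind, relRows) else emptyRelationTable()

    ## classes
    classSubjects <- sort(unique(triples$s[triples$p == rdftype &
        triples$o == paste0(OWL_NS, "Class") & !startsWith(triples$s, "_:")]))
    termRows <- list()
    axioms <- emptyAxiomTable()
    accepted <- 0L
    unsupported <- c(intersectionOf = "owl:intersectionOf",
                     unionOf = "owl:unionOf", complementOf = "owl:complementOf",
                     allValuesFrom = "owl:allValuesFrom",
                     equivalentClass = "owl:equivalentClass")
    for (s in classSubjects) {
        id <- safeCurie(s)
        if (is.na(id)) {
            skip("class IRI outside recognized identifier patterns", s)
            next
        }
        lab <- tfl(s, config$label)
        def <- tfl(s, config$definition)
        desc <- tfl(s, config$description)
        xr <- tfl(s, config$xref)
        ek <- tfl(s, paste0(HOIPV_NS, "entityKind"))
        neg <- tfl(s, paste0(HOIPV_NS, "negated"))
        tax <- tfl(s, paste0(HOIPV_NS, "taxon"))
        stg <- tfl(s, paste0(HOIPV_NS, "stageTag"))
        eqv <- tfi(s, paste0(HOIPV_NS, "equivalentNote"))
        termRows[[length(termRows) + 1L]] <- data.frame(
            id = id,
            label = if (length(lab)) lab[1L] else NA_character_,
            entity_kind = if (length(ek)) ek[1L] else "process",
            definition = if (length(def)) def[1L] else NA_character_,
            description = if (length(desc)) desc[1L] else NA_character_,
            xrefs = if (length(xr)) paste(sort(xr), collapse = ";") else NA_character_,
            negated = length(neg) > 0L && tolower(neg[1L]) == "true",
            taxon = if (length(tax)) tax[1L] else NA_character_,
            stage = if (length(stg)) stg[1L] else NA_character_,
            equivalent_to = if (length(eqv)) safeCurie(eqv[1L]) else NA_character_,
            stringsAsFactors = FALSE)
        ## unsupported class-level constructs -> report
        for (u in names(unsupported)) {
            if (length(tf(s, paste0(OWL_NS, u)))) skip(unsupported[[u]], s)
        }
    }
    ## subclass axioms from any subject (dangling subjects included)
    subRows <- triples[triples$p == paste0(RDFS_NS, "subClassOf"), , drop = FALSE]
    for (i in seq_len(nrow(subRows))) {
        s <- subRows$s[i]; o <- subRows$o[i]
        sid <- safeCurie(s)
        if (is.na(sid)) { skip("subClassOf on unrecognized subject", s); next }
        if (!startsWith(o, "_:")) {
            oid <- safeCurie(o)
            if (is.na(oid)) { skip("subClassOf object outside recognized patterns", o); next }
            axioms <- rbind(axioms, ax_sub(sid, oid, provenance = "imported"))
            accepted <- accepted + 1L
        } else {
            btypes <- types(o)
            if (!(paste0(OWL_NS, "Restriction") %in% btypes)) {
                skip("subClassOf of a non-restriction blank node", s)
                next
            }
            prop <- tfi(o, paste0(OWL_NS, "onProperty"))
            filler <- triples[triples$s == o &
                              triples$p == paste0(OWL_NS, "someValuesFrom"), ,
                              drop = FALSE]
            if (length(tf(o, paste0(OWL_NS, "allValuesFrom")))) {
                skip("universal restriction (owl:allValuesFrom)", s)
                next
            }
            if (length(prop) == 0L || nrow(filler) == 0L) {
                skip("restriction without onProperty/someValuesFrom", s)
                next
            }
            if (startsWith(filler$o[1L], "_:")) {
                skip("restriction with anonymous (nested) filler", s)
                next
            }
            oid <- safeCurie(filler$o[1L])
            if (is.na(oid)) { skip("restriction filler outside recognized patterns", filler$o[1L]); next }
            axioms <- rbind(axioms,
                            ax_ex(sid, localName(prop[1L]), oid,
                                  provenance = "imported"))
            accepted <- accepted + 1L
        }
    }

    terms <- if (length(termRows)) do.call(rbind, termRows) else emptyTermTable()
    ## fill relations referenced by axioms but not declared from the
    ## canonical registry, closing the table under inverse partners and
    ## chain components so the registry invariants hold
    reg <- canonicalRelationRegistry()
    repeat {
        used <- unique(c(axioms$relation[!is.na(axioms$relation)],
                         relations$inverse_of, relations$chain1,
                         relations$chain2))
        used <- used[!is.na(used)]
        missing <- setdiff(used, relations$id)
        if (length(missing) == 0L) break
        known <- reg[reg$id %in% missing, , drop = FALSE]
        relations <- rbind(relations, known)
        for (m in setdiff(missing, reg$id)) {
            ## undeclared, unregistered relation: add a bare row; mirror
            ## the inverse declaration if some present relation points at it
            pointer <- relations$id[!is.na(relations$inverse_of) &
                                        relations$inverse_of == m]
            relations <- rbind(relations,
                               data.frame(id = m, label = NA_character_,
                                          transitive = FALSE,
                                          inverse_of = if (length(pointer))
                                              pointer[1L] else NA_character_,
                                          chain1 = NA_character_,
                                          chain2 = NA_character_,
                                          domain_kind = NA_character_,
                                          range_kind = NA_character_,
                                          stringsAsFactors = FALSE))
        }
    }
    relations <- relations[order(relations$id), , drop = FALSE]
    rownames(relations) <- NULL

    meta <- list()
    ont <- triples$s[triples$p == rdftype & triples$o == paste0(OWL_NS, "Ontology")]
    if (length(ont)) {
        meta$iri <- ont[1L]
        v <- tfl(ont[1L], paste0(OWL_NS, "versionInfo"))
        if (length(v)) meta$version <- v[1L]
    }
    roots <- tfl(if (length(ont)) ont[1L] else "", paste0(HOIPV_NS, "rootClasses"))
    if (length(roots)) meta$roots <- strsplit(roots[1L], ";", fixed = TRUE)[[1]]

    doc <- makeOntologyDocument(terms = terms, relations = relations,
                                axioms = axioms, metadata = meta)
    skipdf <- if (length(skipped)) do.call(rbind, skipped) else
        data.frame(construct = character(0), location = character(0),
                   stringsAsFactors = FALSE)
    report <- methods::new("ParseReport",
                           accepted_axioms = accepted,
                           skipped_constructs = skipdf,
                           dangling_refs = sort(setdiff(
                               unique(c(doc@axioms$subject, doc@axioms$object)),
                               doc@terms$id)))
    list(document = doc, report = report)
}

#' Read an ontology from Turtle or RDF/XML
#'
#' Captures the supported fragment: named-class subsumptions,
#' subclass-of-restriction axioms with \code{owl:someValuesFrom} over a
#' named filler, object-property declarations
#' (\code{owl:TransitiveProperty}, \code{owl:inverseOf},
#' \code{owl:propertyChainAxiom}) and term annotations.  Everything else is
#' skipped and listed in the parse report.  Blank nodes are skolemized
#' deterministically, so two reads of the same bytes yield identical
#' documents and reports.
#'
#' @param source path to a file, or a character scalar of serialized text
#'   when \code{fromText = TRUE}.
#' @param format \code{"turtle"} or \code{"rdfxml"}.
#' @param config annotation IRIs, see \code{\link{annotationConfig}}.
#' @param fromText treat \code{source} as the serialized text itself.
#' @return list with elements \code{document}
#'   (\linkS4class{OntologyDocument}) and \code{report}
#'   (\linkS4class{ParseReport}).
#' @export
readOntology <- function(source, format = c("turtle", "rdfxml"),
                         config = annotationConfig(), fromText = FALSE) {
    format <- match.arg(format)
    text <- if (fromText) source else {
        if (!file.exists(source)) stop("file not found: ", source)
        paste(readLines(source, warn = FALSE, encoding = "UTF-8"),
              collapse = "\n")
    }
    triples <- switch(format, turtle = ttlParse(text), rdfxml = rdfxmlParse(text))
    triplesToDocument(triples, config = config)
}

#' Write an ontology to Turtle or RDF/XML
#'
#' Emits exactly the supported constructs; reading the output back
#' reproduces the document's terms, relations and axioms
#' (order-insensitive; axiom provenance is not serialized).
#'
#' @param doc an \linkS4class{OntologyDocument}.
#' @param path output file; when \code{NULL} the serialized text is
#'   returned invisibly only.
#' @param format \code{"turtle"} or \code{"rdfxml"}.
#' @param config annotation IRIs, see \code{\link{annotationConfig}}.
#' @return the serialized text, invisibly.
#' @export
writeOntology <- function(doc, path = NULL, format = c("turtle", "rdfxml"),
                          config = annotationConfig()) {
    format <- match.arg(format)
    stopifnot(methods::is(doc, "OntologyDocument"))
    bad <- validateDocument(doc)
    fatal <- bad[bad$type == "unknown_relation", , drop = FALSE]
    if (nrow(fatal)) {
        stop("cannot serialize: axioms use undeclared relation(s): ",
             paste(unique(fatal$relation), collapse = ", "))
    }
    triples <- documentToTriples(doc, config = config)
    ## persist the root-class metadata so round-trips keep it
    roots <- ontoMetadata(doc)$roots
    if (!is.null(roots)) {
        iri <- ontoMetadata(doc)$iri
        if (is.null(iri)) iri <- DEFAULT_ONTOLOGY_IRI
        triples <- rbind(triples,
                         data.frame(s = iri, p = paste0(HOIPV_NS, "rootClasses"),
                                    o = paste(roots, collapse = ";"),
                                    o_iri = FALSE, stringsAsFactors = FALSE))
    }
    text <- switch(format,
                   turtle = ttlSerialize(triples, ioPrefixes()),
                   rdfxml = rdfxmlSerialize(triples, ioPrefixes()))
    if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
    invisible(text)
}

#' Export a parse report as JSON
#' @param report a \linkS4class{ParseReport}.
#' @return JSON text.
#' @export
reportToJSON <- function(report) {
    jsonlite::toJSON(list(accepted_axioms = report@accepted_axioms,
                          skipped_constructs = report@skipped_constructs,
                          dangling_refs = report@dangling_refs),
                     auto_unbox = TRUE, pretty = TRUE)
}
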