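#' Construct an OntologyDocument
#'
#' Builds and validates an \linkS4class{OntologyDocument} from term,
#' relation and axiom tables.  Identifiers are normalized to colon-form
#' CURIEs; missing optional columns are filled with defaults.
#'
#' @param terms data.frame with at least \code{id}; optional \code{label},
#'   \code{entity_kind} (default \code{"process"}), \code{definition},
#'   \code{description}, \code{xrefs}, \code{negated}, \code{taxon},
#'   \code{stage}, \code{equivalent_to}.
#' @param relations relation table; defaults to
#'   \code{\link{canonicalRelationRegistry}()}.
#' @param axioms data.frame with \code{subject}, \code{kind},
#'   \code{relation}, \code{object}; optional \code{provenance}
#'   (default \code{"asserted"}).
#' @param metadata named list.
#' @return an \linkS4class{OntologyDocument}.
#' @export
makeOntologyDocument <- function(terms = emptyTermTable(),
                                 relations = canonicalRelationRegistry(),
                                 axioms = emptyAxiomTable(),
                                 metadata = list()) {
    terms <- as.data.frame(terms, stringsAsFactors = FALSE)
    axioms <- as.data.frame(axioms, stringsAsFactors = FALSE)
    fill <- function(df, col, default) {
        if (is.null(df[[col]])) df[[col]] <- rep(default, nrow(df))
        df
    }
    if (nrow(terms)) terms$id <- normalizeCurie(terms$id)
    terms <- fill(terms, "label", NA_character_)
    terms <- fill(terms, "entity_kind", "process")
    terms <- fill(terms, "definition", NA_character_)
    terms <- fill(terms, "description", NA_character_)
    terms <- fill(terms, "xrefs", NA_character_)
    terms <- fill(terms, "negated", FALSE)
    terms <- fill(terms, "taxon", NA_character_)
    terms <- fill(terms, "stage", NA_character_)
    terms <- fill(terms, "equivalent_to", NA_character_)
    terms$negated[is.na(terms$negated)] <- FALSE
    ## keep xref lists in sorted ";"-joined form so serialization round-trips
    terms$xrefs <- vapply(terms$xrefs, function(x) {
        if (is.na(x) || !nzchar(x)) return(NA_character_)
        paste(sort(strsplit(x, ";", fixed = TRUE)[[1]]), collapse = ";")
    }, character(1), USE.NAMES = FALSE)
    terms <- terms[, names(emptyTermTable())]
    if (nrow(axioms)) {
        axioms$subject <- normalizeCurie(axioms$subject)
        axioms$object <- normalizeCurie(axioms$object)
    }
    axioms <- fill(axioms, "relation", NA_character_)
    axioms <- fill(axioms, "provenance", "asserted")
    axioms <- axioms[, names(emptyAxiomTable())]
    axioms <- unique(axioms)
    if (nrow(terms)) terms <- terms[order(terms$id), , drop = FALSE]
    axioms <- axioms[order(axioms$subject, axioms$kind,
                           ifelse(is.na(axioms$relation), "", axioms$relation),
                           axioms$object), , drop = FALSE]
    rownames(terms) <- rownames(axioms) <- NULL
    methods::new("OntologyDocument", terms = terms, relations = relations,
                 axioms = axioms, metadata = metadata)
}

## shorthand used by fixtures and tests
ax_sub <- function(subject, object, provenance = "asserted") {
    data.frame(subject = subject, kind = "subclass_of",
               relation = NA_character_, object = object,
               provenance = provenance, stringsAsFactors = FALSE)
}

ax_ex <- function(subject, relation, object, provenance = "asserted") {
    data.frame(subject = subject, kind = "existential", relation = relation,
               object = object, provenance = provenance,
               stringsAsFactors = FALSE)
}

#' Validate an OntologyDocument against its relation registry
#'
#' Checks every existential axiom against the declared \code{domain_kind}
#' and \code{range_kind} of its relation, reports axioms that reference
#' undeclared relations or classes without a term entry (dangling
#' references), and flags asserted self-causal edges.  Violations are data,
#' not errors: the function always returns a (possibly empty) table.
#'
#' @param doc an \linkS4class{OntologyDocument}.
#' @return data.frame with columns \code{type} (\code{domain_violation},
#'   \code{range_violation}, \code{dangling_reference},
#'   \code{unknown_relation}), \code{subject}, \code{relation},
#'   \code{object}, \code{message}; zero rows if the document is clean.
#' @examples
#' validateDocument(senescenceOntology())   # zero rows
#' @export
validateDocument <- function(doc) {
    stopifnot(methods::is(doc, "OntologyDocument"))
    out <- data.frame(type = character(0), subject = character(0),
                      relation = character(0), object = character(0),
                      message = character(0), stringsAsFactors = FALSE)
    add <- function(type, subject, relation, object, message) {
        rbind(out, data.frame(type = type, subject = subject,
                              relation = relation, object = object,
                              message = message, stringsAsFactors = FALSE))
    }
    tt <- doc@terms
    kind <- stats::setNames(tt$entity_kind, tt$id)
    rel <- doc@relations
    ax <- doc@axioms
    ex <- ax[ax$kind == "existential", , drop = FALSE]
    for (i in seq_len(nrow(ex))) {
        r <- ex$relation[i]
        j <- match(r, rel$id)
        if (is.na(j)) {
            out <- add("unknown_relation", ex$subject[i], r, ex$object[i],
                       paste0("relation '", r, "' is not declared"))
            next
        }
        dk <- rel$domain_kind[j]; rk <- rel$range_kind[j]
        sk <- kind[ex$subject[i]]; ok <- kind[ex$object[i]]
        if (!is.na(dk) && !is.na(sk) && sk != dk) {
            out <- add("domain_violation", ex$subject[i], r, ex$object[i],
                       paste0("subject of ", r, " must be ", dk, ", got ", sk))
        }
        if (!is.na(rk) && !is.na(ok) && ok != rk) {
            out <- add("range_violation", ex$subject[i], r, ex$object[i],
                       paste0("object of ", r, " must be ", rk, ", got ", ok))
        }
    }
    refd <- unique(c(ax$subject, ax$object))
    dangling <- setdiff(refd, tt$id)
    for (d in dangling) {
        out <- add("dangling_reference", d, NA_character_, NA_character_,
                   paste0("class ", d, " is referenced by an axiom but not declared"))
    }
    rownames(out) <- NULL
    out
}

## order-insensitive equality of two documents on (terms, relations, axioms);
## axiom provenance is ignored because serialization does not preserve it.
sameOntology <- function(a, b) {
    norm_ax <- function(d) {
        x <- d@axioms[, c("subject", "kind", "relation", "object")]
        x <- x[do.call(order, x), , drop = FALSE]
        rownames(x) <- NULL
        x
    }
    norm_terms <- function(d) {
        x <- d@terms[order(d@terms$id), , drop = FALSE]
        rownames(x) <- NULL
        x
    }
    norm_rel <- function(d) {
        x <- d@relations[order(d@relations$id), , drop = FALSE]
        rownames(x) <- NULL
        x
    }
    isTRUE(all.equal(norm_ax(a), norm_ax(b))) &&
        isTRUE(all.equal(norm_terms(a), norm_terms(b))) &&
        isTRUE(all.equal(norm_rel(a), norm_rel(b)))
}
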