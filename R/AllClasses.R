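## Central S4 containers.  All tabular slots are plain data.frames with a
## fixed column contract (see the emptyX() constructors below); identifiers
## are always stored in normalized CURIE form.

ENTITY_KINDS <- c("course", "process", "material_entity", "role", "disease",
                  "symptom", "phenotype", "anatomical_entity", "other")

AXIOM_KINDS <- c("subclass_of", "existential")

STAGES <- c("stress_demand", "stress_response", "imbalance", "outcome")

emptyTermTable <- function() {
    data.frame(id = character(0), label = character(0),
               entity_kind = character(0), definition = character(0),
               description = character(0), xrefs = character(0),
               negated = logical(0), taxon = character(0),
               stage = character(0), equivalent_to = character(0),
               stringsAsFactors = FALSE)
}

emptyRelationTable <- function() {
    data.frame(id = character(0), label = character(0),
               transitive = logical(0), inverse_of = character(0),
               chain1 = character(0), chain2 = character(0),
               domain_kind = character(0), range_kind = character(0),
               stringsAsFactors = FALSE)
}

emptyAxiomTable <- function() {
    data.frame(subject = character(0), kind = character(0),
               relation = character(0), object = character(0),
               provenance = character(0), stringsAsFactors = FALSE)
}

#' OntologyDocument: a typed ontology fragment
#'
#' In-memory model of the OWL-DL fragment this package works with: named
#' classes (terms) with annotations, object properties (relations) with
#' logical characteristics, and axioms that are either named-class
#' subsumptions or existential restrictions with a named filler, read as
#' typed class-level edges.
#'
#' @slot terms data.frame with columns \code{id}, \code{label},
#'   \code{entity_kind}, \code{definition}, \code{description},
#'   \code{xrefs} (";"-separated), \code{negated}, \code{taxon},
#'   \code{stage}, \code{equivalent_to}.
#' @slot relations data.frame with columns \code{id}, \code{label},
#'   \code{transitive}, \code{inverse_of}, \code{chain1}, \code{chain2},
#'   \code{domain_kind}, \code{range_kind}.
#' @slot axioms data.frame with columns \code{subject}, \code{kind}
#'   (\code{subclass_of} or \code{existential}), \code{relation} (NA for
#'   subsumptions), \code{object}, \code{provenance}.
#' @slot metadata named list of free-form metadata (version, source,
#'   \code{roots}, ...).
#' @export
setClass("OntologyDocument",
         representation(terms = "data.frame", relations = "data.frame",
                        axioms = "data.frame", metadata = "list"),
         prototype(terms = emptyTermTable(), relations = emptyRelationTable(),
                   axioms = emptyAxiomTable(), metadata = list()))

setValidity("OntologyDocument", function(object) {
    msg <- character(0)
    tt <- object@terms
    if (anyDuplicated(tt$id)) {
        msg <- c(msg, paste("duplicated term ids:",
                            paste(unique(tt$id[duplicated(tt$id)]), collapse = ", ")))
    }
    bad <- setdiff(unique(tt$entity_kind), ENTITY_KINDS)
    if (length(bad)) msg <- c(msg, paste("unknown entity_kind:", paste(bad, collapse = ", ")))
    ax <- object@axioms
    if (nrow(ax)) {
        if (!all(ax$kind %in% AXIOM_KINDS)) msg <- c(msg, "axiom kind must be subclass_of or existential")
        sub <- ax$kind == "subclass_of"
        if (any(sub & !is.na(ax$relation))) msg <- c(msg, "subclass_of axioms must not carry a relation")
        if (any(!sub & is.na(ax$relation))) msg <- c(msg, "existential axioms require a relation")
        selfCause <- !sub & ax$relation %in% c("has_result", "has_cause") &
            ax$subject == ax$object
        if (any(selfCause)) msg <- c(msg, "asserted self-causal existential axioms are not allowed")
    }
    rel <- object@relations
    if (nrow(rel)) {
        has_inv <- !is.na(rel$inverse_of)
        for (i in which(has_inv)) {
            j <- match(rel$inverse_of[i], rel$id)
            if (is.na(j) || is.na(rel$inverse_of[j]) || rel$inverse_of[j] != rel$id[i]) {
                msg <- c(msg, paste0("inverse_of not symmetric for relation ", rel$id[i]))
            }
        }
        chain_one_sided <- xor(is.na(rel$chain1), is.na(rel$chain2))
        if (any(chain_one_sided)) msg <- c(msg, "a relation chain must have exactly two elements")
    }
    if (length(msg)) msg else TRUE
})

#' ParseReport: what an ontology read accepted and skipped
#'
#' @slot accepted_axioms number of subsumption/existential axioms captured.
#' @slot skipped_constructs data.frame (\code{construct}, \code{location})
#'   of RDF constructs outside the supported fragment.
#' @slot dangling_refs CURIEs referenced by axioms but not declared as terms.
#' @export
setClass("ParseReport",
         representation(accepted_axioms = "integer",
                        skipped_constructs = "data.frame",
                        dangling_refs = "character"),
         prototype(accepted_axioms = 0L,
                   skipped_constructs = data.frame(construct = character(0),
                                                   location = character(0),
                                                   stringsAsFactors = FALSE),
                   dangling_refs = character(0)))

#' InferredGraph: the materialized closure of a document
#'
#' @slot edges data.frame (\code{subject}, \code{relation}, \code{object},
#'   \code{status} asserted/inferred, \code{derivation} list column: rule tag
#'   plus premise references; non-empty for every inferred edge).
#' @slot subsumptions data.frame (\code{sub}, \code{super}), transitively
#'   closed over the asserted subclass axioms (reflexive pairs are implicit).
#' @slot doc the source \linkS4class{OntologyDocument}.
#' @export
setClass("InferredGraph",
         representation(edges = "data.frame", subsumptions = "data.frame",
                        doc = "OntologyDocument"))

setValidity("InferredGraph", function(object) {
    e <- object@edges
    need <- c("subject", "relation", "object", "status", "derivation")
    if (!all(need %in% names(e))) return("edges must have subject/relation/object/status/derivation")
    inf <- e$status == "inferred"
    if (any(inf & lengths(e$derivation) == 0L)) return("inferred edges require a non-empty derivation")
    TRUE
})

#' CourseGraph: a per-course causal network ready for query and export
#'
#' @slot course_id identifier of the course (or a descriptive label for
#'   merged/generalized graphs).
#' @slot nodes data.frame (\code{id}, \code{entity_kind}, \code{origin}
#'   direct/inherited/specialized).
#' @slot edges data.frame (\code{subject}, \code{relation}, \code{object},
#'   \code{status}); \code{relation == "is_a"} marks subsumption display
#'   edges.
#' @slot stage_tags named character vector (node id -> stage).
#' @slot termInfo data.frame subset of the source document's term table for
#'   the graph's nodes, so exporters are self-contained.
#' @export
setClass("CourseGraph",
         representation(course_id = "character", nodes = "data.frame",
                        edges = "data.frame", stage_tags = "character",
                        termInfo = "data.frame"))

setValidity("CourseGraph", function(object) {
    n <- object@nodes; e <- object@edges
    if (nrow(e) && !all(c(e$subject, e$object) %in% n$id)) {
        return("every edge endpoint must be a node of the graph")
    }
    if (nrow(n) && !all(n$origin %in% c("direct", "inherited", "specialized"))) {
        return("node origin must be direct, inherited or specialized")
    }
    TRUE
})

#' PatternReport: the four-stage homeostatic-imbalance check for one course
#'
#' @slot course course identifier.
#' @slot stages_present stages found among the course members.
#' @slot ordered_witness character vector of four member processes, one per
#'   stage in order (stress demand, stress response, imbalance, outcome),
#'   with every consecutive pair causally entailed; length 0 if none exists.
#' @slot missing stages with no tagged member.
#' @export
setClass("PatternReport",
         representation(course = "character", stages_present = "character",
                        ordered_witness = "character", missing = "character"))

setValidity("PatternReport", function(object) {
    if (!setequal(union(object@stages_present, object@missing), STAGES)) {
        return("stages_present and missing must partition the four stages")
    }
    TRUE
})
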