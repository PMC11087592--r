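#' @name accessors
#' @title Accessors for hoipr S4 objects
#' @description Slot accessors; user code should use these rather than
#'   reaching into slots with \code{@}.
#' @param x an object.
#' @return The corresponding table or value.
NULL

#' @rdname accessors
#' @export
setGeneric("ontoTerms", function(x) standardGeneric("ontoTerms"))
#' @rdname accessors
#' @export
setGeneric("ontoRelations", function(x) standardGeneric("ontoRelations"))
#' @rdname accessors
#' @export
setGeneric("ontoAxioms", function(x) standardGeneric("ontoAxioms"))
#' @rdname accessors
#' @export
setGeneric("ontoMetadata", function(x) standardGeneric("ontoMetadata"))
#' @rdname accessors
#' @export
setGeneric("inferredEdges", function(x) standardGeneric("inferredEdges"))
#' @rdname accessors
#' @export
setGeneric("subsumptions", function(x) standardGeneric("subsumptions"))
#' @rdname accessors
#' @export
setGeneric("sourceDocument", function(x) standardGeneric("sourceDocument"))
#' @rdname accessors
#' @export
setGeneric("courseId", function(x) standardGeneric("courseId"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("stageTags", function(x) standardGeneric("stageTags"))

#' @rdname accessors
#' @export
setMethod("ontoTerms", "OntologyDocument", function(x) x@terms)
#' @rdname accessors
#' @export
setMethod("ontoRelations", "OntologyDocument", function(x) x@relations)
#' @rdname accessors
#' @export
setMethod("ontoAxioms", "OntologyDocument", function(x) x@axioms)
#' @rdname accessors
#' @export
setMethod("ontoMetadata", "OntologyDocument", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("inferredEdges", "InferredGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("subsumptions", "InferredGraph", function(x) x@subsumptions)
#' @rdname accessors
#' @export
setMethod("sourceDocument", "InferredGraph", function(x) x@doc)
#' @rdname accessors
#' @export
setMethod("courseId", "CourseGraph", function(x) x@course_id)
#' @rdname accessors
#' @export
setMethod("graphNodes", "CourseGraph", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("graphEdges", "CourseGraph", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("stageTags", "CourseGraph", function(x) x@stage_tags)
#' @rdname accessors
#' @export
setMethod("stageTags", "OntologyDocument", function(x) {
    tt <- x@terms
    keep <- !is.na(tt$stage)
    stats::setNames(tt$stage[keep], tt$id[keep])
})

setMethod("show", "OntologyDocument", function(object) {
    ax <- object@axioms
    cat("OntologyDocument with", nrow(object@terms), "terms,",
        nrow(object@relations), "relations,",
        sum(ax$kind == "subclass_of"), "subclass axioms,",
        sum(ax$kind == "existential"), "existential axioms\n")
    if (length(object@metadata)) {
        cat("metadata:", paste(names(object@metadata), collapse = ", "), "\n")
    }
})

setMethod("show", "ParseReport", function(object) {
    cat("ParseReport:", object@accepted_axioms, "axioms accepted;",
        nrow(object@skipped_constructs), "constructs skipped;",
        length(object@dangling_refs), "dangling references\n")
})

setMethod("show", "InferredGraph", function(object) {
    e <- object@edges
    cat("InferredGraph:", sum(e$status == "asserted"), "asserted +",
        sum(e$status == "inferred"), "inferred edges;",
        nrow(object@subsumptions), "subsumption pairs\n")
})

setMethod("show", "CourseGraph", function(object) {
    cat("CourseGraph for", object@course_id, "with",
        nrow(object@nodes), "nodes and", nrow(object@edges), "edges\n")
})

setMethod("show", "PatternReport", function(object) {
    cat("PatternReport for", object@course, "\n  stages present:",
        if (length(object@stages_present)) paste(object@stages_present, collapse = ", ") else "(none)",
        "\n  missing:",
        if (length(object@missing)) paste(object@missing, collapse = ", ") else "(none)", "\n")
    if (length(object@ordered_witness)) {
        cat("  witness:", paste(object@ordered_witness, collapse = " -> "), "\n")
    }
})
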