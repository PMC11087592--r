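## The four-stage homeostatic-imbalance pattern: stress (functional
## demand), stress response (functioning process), imbalance, outcome.

#' The four homeostatic-imbalance stages
#' @return character vector of the stage names, in causal order.
#' @export
imbalanceStages <- function() STAGES

#' Tag a process with a homeostatic-imbalance stage
#'
#' Stages are curator-supplied annotations, not inferred from class names.
#' Re-assigning a different stage requires \code{force = TRUE}; assigning
#' the same stage again is a no-op.
#'
#' @param doc an \linkS4class{OntologyDocument}.
#' @param process process CURIE.
#' @param stage one of \code{\link{imbalanceStages}()}.
#' @param force overwrite a conflicting earlier assignment.
#' @return the updated document.
#' @export
assignStage <- function(doc, process, stage, force = FALSE) {
    stopifnot(methods::is(doc, "OntologyDocument"))
    stage <- match.arg(stage, STAGES)
    process <- normalizeCurie(process)
    i <- match(process, doc@terms$id)
    if (is.na(i)) stop("unknown process: ", process)
    cur <- doc@terms$stage[i]
    if (!is.na(cur) && cur != stage && !force) {
        stop("process ", process, " already carries stage '", cur,
             "'; use force = TRUE to re-assign")
    }
    doc@terms$stage[i] <- stage
    doc
}

#' Heuristic stage pre-tagger
#'
#' Convenience only, always overridable by \code{\link{assignStage}}:
#' labels containing "demand" or "stress" (but not "stress response") are
#' pre-tagged \code{stress_demand}; subclasses of a supplied
#' stress-response class are pre-tagged \code{stress_response}.  Existing
#' tags are never overwritten.
#'
#' @param doc an \linkS4class{OntologyDocument}.
#' @param responseRoot optional CURIE of the stress-response functional
#'   process; its subclasses get \code{stress_response}.
#' @return the updated document.
#' @export
preTagStages <- function(doc, responseRoot = NULL) {
    tt <- doc@terms
    untag <- is.na(tt$stage)
    demandish <- grepl("demand", tt$label, ignore.case = TRUE) |
        (grepl("stress", tt$label, ignore.case = TRUE) &
             !grepl("stress response", tt$label, ignore.case = TRUE))
    doc@terms$stage[untag & demandish & tt$entity_kind == "process"] <-
        "stress_demand"
    if (!is.null(responseRoot)) {
        responseRoot <- normalizeCurie(responseRoot)
        ax <- doc@axioms
        subs <- subsumptionClosure(ax[ax$kind == "subclass_of", , drop = FALSE])
        kids <- subs$sub[subs$super == responseRoot]
        hit <- doc@terms$id %in% kids & is.na(doc@terms$stage)
        doc@terms$stage[hit] <- "stress_response"
    }
    doc
}

#' Check a course for the four-stage imbalance pattern
#'
#' Reports which stages are present among the course members and searches
#' for an ordered witness: one member per stage, in stage order, with
#' every consecutive pair connected by an entailed causal
#' (\code{has_result}) edge — entailment, not a direct edge, matching the
#' coarse arrows of the unified model.  The lexicographically first
#' witness under CURIE order is returned.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param course course CURIE.
#' @return a \linkS4class{PatternReport}.
#' @examples
#' g <- materialize(senescenceOntology())
#' checkCoursePattern(g, "HOIP:0060267")
#' @export
checkCoursePattern <- function(graph, course) {
    course <- normalizeCurie(course)
    doc <- graph@doc
    members <- courseMembers(graph, course)$id
    tags <- stageTags(doc)
    tags <- tags[names(tags) %in% members]
    byStage <- lapply(STAGES, function(s) sort(names(tags)[tags == s]))
    names(byStage) <- STAGES
    present <- STAGES[lengths(byStage) > 0L]
    missing <- setdiff(STAGES, present)

    witness <- character(0)
    if (length(missing) == 0L) {
        hasEdge <- function(a, b) {
            any(graph@edges$subject == a & graph@edges$relation == "has_result" &
                    graph@edges$object == b)
        }
        found <- FALSE
        for (p1 in byStage$stress_demand) {
            if (found) break
            for (p2 in byStage$stress_response) {
                if (found) break
                if (!hasEdge(p1, p2)) next
                for (p3 in byStage$imbalance) {
                    if (found) break
                    if (!hasEdge(p2, p3)) next
                    for (p4 in byStage$outcome) {
                        if (hasEdge(p3, p4)) {
                            witness <- c(p1, p2, p3, p4)
                            found <- TRUE
                            break
                        }
                    }
                }
            }
        }
    }
    methods::new("PatternReport", course = course, stages_present = present,
                 ordered_witness = witness, missing = missing)
}

#' Export a pattern report as JSON
#' @param report a \linkS4class{PatternReport}.
#' @return JSON text.
#' @export
patternToJSON <- function(report) {
    jsonlite::toJSON(list(course = report@course,
                          stages_present = report@stages_present,
                          ordered_witness = report@ordered_witness,
                          missing = report@missing),
                     auto_unbox = TRUE, pretty = TRUE)
}
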