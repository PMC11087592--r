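## Course membership, inheritance/specialization and causal queries.

termKind <- function(doc, id) {
    k <- doc@terms$entity_kind[match(id, doc@terms$id)]
    if (is.na(k)) stop("unknown class: ", id)
    k
}

assertedParts <- function(doc, course) {
    ax <- doc@axioms
    sort(unique(c(
        ax$object[ax$kind == "existential" & ax$relation == "has_part" &
                      ax$subject == course],
        ax$subject[ax$kind == "existential" & ax$relation == "part_of" &
                       ax$object == course])))
}

## ancestor courses, closest first (BFS over asserted subclass axioms)
courseAncestors <- function(doc, course) {
    ax <- doc@axioms
    sub <- ax[ax$kind == "subclass_of", , drop = FALSE]
    seen <- character(0)
    frontier <- course
    repeat {
        nxt <- sort(unique(sub$object[sub$subject %in% frontier]))
        nxt <- setdiff(nxt, c(seen, course))
        if (length(nxt) == 0L) break
        seen <- c(seen, nxt)
        frontier <- nxt
    }
    seen
}

isProperSub <- function(graph, sub, super) {
    any(graph@subsumptions$sub == sub & graph@subsumptions$super == super)
}

#' Course membership with inheritance and specialization
#'
#' A course's members are its direct \code{has_part} fillers plus the parts
#' inherited from every supercourse.  An inherited part is replaced when a
#' closer course asserts a part that is a proper subclass of it (e.g.
#' sustained cellular senescence replacing plain cellular senescence in the
#' chronic course); the replacing part's origin is then recorded as
#' \code{specialized} and the replaced general class is listed in
#' \code{replaces}.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param course a course CURIE (entity kind must be \code{course}).
#' @return data.frame (\code{id}, \code{origin}, \code{replaces}) sorted by
#'   id; origin is \code{direct}, \code{inherited} or \code{specialized}.
#' @examples
#' g <- materialize(senescenceOntology())
#' courseMembers(g, "HOIP:0060195")
#' @export
courseMembers <- function(graph, course) {
    stopifnot(methods::is(graph, "InferredGraph"))
    doc <- graph@doc
    course <- normalizeCurie(course)
    if (termKind(doc, course) != "course") {
        stop(course, " is not a course (entity_kind = ",
             termKind(doc, course), ")")
    }
    ids <- character(0); origin <- character(0); replaces <- character(0)
    addMember <- function(p, org) {
        ids <<- c(ids, p); origin <<- c(origin, org)
        replaces <<- c(replaces, NA_character_)
    }
    for (p in assertedParts(doc, course)) addMember(p, "direct")
    for (a in courseAncestors(doc, course)) {
        for (p in assertedParts(doc, a)) {
            if (p %in% ids) next
            specializers <- ids[vapply(ids, isProperSub, logical(1),
                                       super = p, graph = graph)]
            if (length(specializers)) {
                for (sp in specializers) {
                    i <- match(sp, ids)
                    if (origin[i] == "direct") {
                        origin[i] <- "specialized"
                        replaces[i] <- p
                    }
                }
            } else {
                addMember(p, "inherited")
            }
        }
    }
    out <- data.frame(id = ids, origin = origin, replaces = replaces,
                      stringsAsFactors = FALSE)
    out <- out[order(out$id), , drop = FALSE]
    rownames(out) <- NULL
    out
}

scopeToCourse <- function(graph, ids, course, process) {
    if (is.null(course)) return(sort(ids))
    m <- courseMembers(graph, course)
    if (!(process %in% m$id)) {
        stop("process ", process, " is not a member of course ", course)
    }
    sort(intersect(ids, m$id))
}

#' Entailed causes of a process
#'
#' All classes X with an entailed \code{X has_result process} edge (direct
#' or transitive).  With \code{course} given, the result is restricted to
#' that course's members and the process itself must be a member.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param process a process CURIE.
#' @param course optional course CURIE scoping the query.
#' @return sorted character vector of CURIEs.
#' @examples
#' g <- materialize(senescenceOntology())
#' causesOf(g, "HOIP:0060427", course = "HOIP:0060423")
#' @export
causesOf <- function(graph, process, course = NULL) {
    process <- normalizeCurie(process)
    termKind(graph@doc, process)
    if (!is.null(course)) course <- normalizeCurie(course)
    e <- graph@edges
    causes <- unique(e$subject[e$relation == "has_result" & e$object == process])
    scopeToCourse(graph, causes, course, process)
}

#' Entailed results of a process
#'
#' Mirror of \code{\link{causesOf}} through the inverse causal relation:
#' all X with an entailed \code{X has_cause process} edge.
#'
#' @inheritParams causesOf
#' @return sorted character vector of CURIEs.
#' @export
resultsOf <- function(graph, process, course = NULL) {
    process <- normalizeCurie(process)
    termKind(graph@doc, process)
    if (!is.null(course)) course <- normalizeCurie(course)
    e <- graph@edges
    results <- unique(e$subject[e$relation == "has_cause" & e$object == process])
    scopeToCourse(graph, results, course, process)
}

#' Simple causal paths over asserted edges
#'
#' Enumerates all simple paths of asserted \code{has_result} edges from
#' \code{src} to \code{dst} with at most \code{maxLen} edges.  Inferred
#' transitive edges are deliberately excluded (they would collapse every
#' path to length one).  \code{src == dst} returns the single trivial path
#' by convention.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param src,dst process CURIEs.
#' @param maxLen maximum number of edges per path (>= 1).
#' @return list of character vectors (node sequences), sorted
#'   lexicographically.
#' @export
causalPaths <- function(graph, src, dst, maxLen) {
    src <- normalizeCurie(src); dst <- normalizeCurie(dst)
    termKind(graph@doc, src); termKind(graph@doc, dst)
    stopifnot(maxLen >= 1L)
    if (src == dst) return(list(src))
    ax <- graph@doc@axioms
    ## asserted causal edges, viewed in result orientation
    e <- ax[ax$kind == "existential" & ax$relation %in%
                c("has_result", "has_cause"), , drop = FALSE]
    flip <- e$relation == "has_cause"
    e <- unique(data.frame(subject = ifelse(flip, e$object, e$subject),
                           object = ifelse(flip, e$subject, e$object),
                           stringsAsFactors = FALSE))
    verts <- sort(unique(c(e$subject, e$object, src, dst)))
    if (nrow(e) == 0L) return(list())
    ig <- igraph::graph_from_data_frame(e[, c("subject", "object")],
                                        directed = TRUE,
                                        vertices = data.frame(name = verts))
    paths <- igraph::all_simple_paths(ig, from = src, to = dst,
                                      mode = "out", cutoff = maxLen)
    out <- lapply(paths, function(p) igraph::V(ig)$name[as.integer(p)])
    keys <- vapply(out, paste, character(1), collapse = "\r")
    out[order(keys)]
}

#' Cross-course results of a process class
#'
#' For every course in the document, the entailed results of the process
#' class — including results reached through its course-specific
#' subclasses (e.g. per-course IL-8 signaling variants) — restricted to
#' that course's members.  Courses with no results are omitted.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param processClass a process CURIE.
#' @return named list: course CURIE -> sorted character vector of results.
#' @examples
#' g <- materialize(senescenceOntology())
#' crossCourseResults(g, "HOIP:0041903")
#' @export
crossCourseResults <- function(graph, processClass) {
    processClass <- normalizeCurie(processClass)
    doc <- graph@doc
    termKind(doc, processClass)
    subs <- graph@subsumptions
    variants <- c(processClass, subs$sub[subs$super == processClass])
    e <- graph@edges
    courses <- sort(doc@terms$id[doc@terms$entity_kind == "course"])
    out <- list()
    for (cc in courses) {
        m <- courseMembers(graph, cc)
        inCourse <- intersect(variants, m$id)
        if (length(inCourse) == 0L) next
        res <- unique(e$object[e$relation == "has_result" &
                                   e$subject %in% inCourse])
        res <- sort(intersect(res, m$id))
        if (length(res)) out[[cc]] <- res
    }
    out
}

ancestorsOf <- function(graph, x, reflexive = TRUE) {
    a <- graph@subsumptions$super[graph@subsumptions$sub == x]
    if (reflexive) c(x, a) else a
}

#' Common generalized processes of two courses
#'
#' Pairs of members, one per course, that share a non-trivial superclass
#' (their least common ancestor in the subsumption hierarchy).  Trivial
#' hub/root classes — by default the document's \code{metadata$roots} — are
#' excluded, as are identical members.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param courseA,courseB course CURIEs.
#' @param exclude superclasses never reported; defaults to
#'   \code{ontoMetadata(doc)$roots}.
#' @return data.frame (\code{superclass}, \code{memberA}, \code{memberB}),
#'   sorted; the superclass is the least common ancestor (ties broken by
#'   identifier order).
#' @export
commonGeneralizedProcesses <- function(graph, courseA, courseB,
                                       exclude = NULL) {
    courseA <- normalizeCurie(courseA); courseB <- normalizeCurie(courseB)
    if (is.null(exclude)) {
        exclude <- ontoMetadata(graph@doc)$roots
        if (is.null(exclude)) exclude <- character(0)
    }
    mA <- courseMembers(graph, courseA)$id
    mB <- courseMembers(graph, courseB)$id
    rows <- list()
    for (a in mA) {
        ancA <- setdiff(ancestorsOf(graph, a), exclude)
        for (b in mB) {
            if (a == b) next
            common <- setdiff(intersect(ancA, ancestorsOf(graph, b)), exclude)
            if (length(common) == 0L) next
            ## least under the subsumption order: no other common ancestor
            ## strictly below it
            least <- common[vapply(common, function(s) {
                !any(vapply(setdiff(common, s), isProperSub, logical(1),
                            super = s, graph = graph))
            }, logical(1))]
            least <- sort(least)[1L]
            rows[[length(rows) + 1L]] <- data.frame(
                superclass = least, memberA = a, memberB = b,
                stringsAsFactors = FALSE)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(superclass = character(0), memberA = character(0),
                   memberB = character(0), stringsAsFactors = FALSE)
    out <- out[order(out$superclass, out$memberA, out$memberB), , drop = FALSE]
    rownames(out) <- NULL
    out
}

courseGraphTermInfo <- function(doc, ids) {
    tt <- doc@terms[doc@terms$id %in% ids, , drop = FALSE]
    tt <- tt[order(tt$id), , drop = FALSE]
    rownames(tt) <- NULL
    tt
}

#' Per-course causal graph for export
#'
#' Assembles the \linkS4class{CourseGraph} of one course: its members as
#' nodes (with origin annotations), the asserted typed edges among them,
#' optionally the members of all supercourses (the cross-course view used
#' for visualization) and optionally dotted \code{is_a} display edges for
#' subsumption pairs among included nodes.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param course course CURIE.
#' @param includeSupercourses also include every supercourse's members.
#' @param isaEdges emit \code{is_a} edges for asserted subsumptions among
#'   included nodes (default: only in the cross-course view).
#' @param includeInferred also include inferred (transitive) causal edges.
#' @return a \linkS4class{CourseGraph}.
#' @export
courseGraph <- function(graph, course, includeSupercourses = FALSE,
                        isaEdges = includeSupercourses,
                        includeInferred = FALSE) {
    course <- normalizeCurie(course)
    doc <- graph@doc
    members <- courseMembers(graph, course)
    if (includeSupercourses) {
        for (a in courseAncestors(doc, course)) {
            if (termKind(doc, a) != "course") next
            ma <- courseMembers(graph, a)
            extra <- ma[!(ma$id %in% members$id), , drop = FALSE]
            if (nrow(extra)) {
                extra$origin <- "inherited"
                members <- rbind(members, extra)
            }
        }
    }
    ids <- members$id
    ## attachments (outputs, roles, locations, symptoms, diseases) hang off
    ## member processes and are pulled into the graph
    ax <- doc@axioms
    attach_rel <- c("has_output", "has_role", "occurs_in",
                    "manifests_symptom", "realizes_disease")
    att <- ax[ax$kind == "existential" & ax$relation %in% attach_rel &
                  ax$subject %in% ids, , drop = FALSE]
    attIds <- setdiff(unique(att$object), ids)
    if (length(attIds)) {
        members <- rbind(members,
                         data.frame(id = attIds, origin = "direct",
                                    replaces = NA_character_,
                                    stringsAsFactors = FALSE))
        ids <- members$id
    }
    kind <- doc@terms$entity_kind[match(ids, doc@terms$id)]
    nodes <- data.frame(id = ids, entity_kind = kind, origin = members$origin,
                        stringsAsFactors = FALSE)
    nodes <- nodes[order(nodes$id), , drop = FALSE]

    ex <- ax[ax$kind == "existential" & ax$subject %in% ids &
                 ax$object %in% ids & ax$relation != "part_of", , drop = FALSE]
    edges <- data.frame(subject = ex$subject, relation = ex$relation,
                        object = ex$object, status = "asserted",
                        stringsAsFactors = FALSE)
    if (includeInferred) {
        e <- graph@edges
        inf <- e[e$status == "inferred" & e$relation == "has_result" &
                     e$subject %in% ids & e$object %in% ids, , drop = FALSE]
        if (nrow(inf)) {
            edges <- rbind(edges,
                           data.frame(subject = inf$subject,
                                      relation = inf$relation,
                                      object = inf$object, status = "inferred",
                                      stringsAsFactors = FALSE))
        }
    }
    if (isaEdges) {
        sub <- ax[ax$kind == "subclass_of" & ax$subject %in% ids &
                      ax$object %in% ids, , drop = FALSE]
        if (nrow(sub)) {
            edges <- rbind(edges,
                           data.frame(subject = sub$subject, relation = "is_a",
                                      object = sub$object, status = "asserted",
                                      stringsAsFactors = FALSE))
        }
    }
    edges <- unique(edges)
    edges <- edges[order(edges$subject, edges$relation, edges$object), ,
                   drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    tags <- stageTags(doc)
    tags <- tags[names(tags) %in% nodes$id]
    methods::new("CourseGraph", course_id = course, nodes = nodes,
                 edges = edges, stage_tags = tags,
                 termInfo = courseGraphTermInfo(doc, nodes$id))
}

#' Generalized causal network across courses
#'
#' Merges the causal structure of several courses at a chosen abstraction
#' level: each member process is mapped to a superclass (identity where the
#' map is silent), and an edge connects two superclasses iff some pair of
#' mapped members carries an entailed \code{has_result} edge.
#'
#' @param graph a materialized \linkS4class{InferredGraph}.
#' @param courses character vector of course CURIEs.
#' @param abstraction named character vector: member CURIE -> superclass
#'   CURIE.  Every target must subsume its member.
#' @return a \linkS4class{CourseGraph} whose nodes are the abstraction
#'   targets.
#' @export
generalizedCausalNetwork <- function(graph, courses, abstraction = character(0)) {
    courses <- normalizeCurie(courses)
    doc <- graph@doc
    if (length(abstraction)) {
        abstraction <- stats::setNames(normalizeCurie(unname(abstraction)),
                                       normalizeCurie(names(abstraction)))
        for (m in names(abstraction)) {
            tgt <- abstraction[[m]]
            if (tgt != m && !isProperSub(graph, m, tgt)) {
                stop("abstraction target ", tgt, " is not an ancestor of ", m)
            }
        }
    }
    members <- sort(unique(unlist(lapply(courses, function(cc)
        courseMembers(graph, cc)$id))))
    mapTo <- function(x) if (x %in% names(abstraction)) abstraction[[x]] else x
    e <- graph@edges
    causal <- e[e$relation == "has_result" & e$subject %in% members &
                    e$object %in% members, , drop = FALSE]
    edges <- unique(data.frame(
        subject = vapply(causal$subject, mapTo, character(1), USE.NAMES = FALSE),
        object = vapply(causal$object, mapTo, character(1), USE.NAMES = FALSE),
        stringsAsFactors = FALSE))
    edges <- edges[edges$subject != edges$object, , drop = FALSE]
    edges <- data.frame(subject = edges$subject,
                        relation = rep("has_result", nrow(edges)),
                        object = edges$object,
                        status = rep("inferred", nrow(edges)),
                        stringsAsFactors = FALSE)
    ids <- sort(unique(c(vapply(members, mapTo, character(1), USE.NAMES = FALSE),
                         edges$subject, edges$object)))
    kind <- doc@terms$entity_kind[match(ids, doc@terms$id)]
    nodes <- data.frame(id = ids, entity_kind = kind,
                        origin = rep("direct", length(ids)),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$subject, edges$relation, edges$object), ,
                   drop = FALSE]
    rownames(nodes) <- rownames(edges) <- NULL
    methods::new("CourseGraph",
                 course_id = paste0("generalized(",
                                    paste(courses, collapse = ","), ")"),
                 nodes = nodes, edges = edges,
                 stage_tags = character(0),
                 termInfo = courseGraphTermInfo(doc, ids))
}
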