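## Materializing reasoner for the supported fragment.
##
## Completion rules (over a finite class/relation universe; every rule
## only adds facts, so termination is guaranteed even with causal cycles):
##   R1  A subClassOf B, B subClassOf C            =>  A subClassOf C
##   R2  A subClassOf B, B -R-> C                  =>  A -R-> C
##   R3  A -R-> B, B subClassOf C                  =>  A -R-> C
##   R4  R transitive, A -R-> B, B -R-> C          =>  A -R-> C
##   R5  S == chain(R1, R2), A -R1-> B, B -R2-> C  =>  A -S-> C
##   R6  R inverseOf R', A -R-> B                  =>  B -R'-> A
##
## Rules R2-R5 are evaluated on a canonical orientation per declared
## inverse pair (has_result for the causal pair, has_part for the
## part-whole pair); axioms asserted in the inverse orientation are
## canonicalized at intake, and R6 completes the inverse orientation as a
## final pass.  Running R6 inside the fixpoint instead would let edges
## zig-zag up AND down the class hierarchy through the inverse relation,
## equating causal edges across sibling classes and creating self-causes
## on acyclic graphs — unsound for the causal-graph reading; the staged
## evaluation preserves inverse coherence (A -R-> B entailed iff
## B -R'-> A entailed) while propagating restrictions only subject-down /
## filler-up, as a DL reasoner does.
##
## Evaluation is semi-naive: only newly derived edges re-fire rules, in
## deterministic (sorted) order, so derivation traces are reproducible.

edgeKey <- function(s, r, o) paste(s, r, o, sep = "\r")

## transitive closure of asserted subclass pairs (proper pairs only;
## reflexive subsumption stays implicit), via per-node DFS over an
## adjacency list.
subsumptionClosure <- function(pairs) {
    if (nrow(pairs) == 0L) {
        return(data.frame(sub = character(0), super = character(0),
                          stringsAsFactors = FALSE))
    }
    adj <- split(pairs$object, pairs$subject)
    nodes <- sort(unique(pairs$subject))
    res_sub <- character(0); res_super <- character(0)
    for (n in nodes) {
        seen <- character(0)
        stack <- adj[[n]]
        while (length(stack)) {
            x <- stack[[1L]]; stack <- stack[-1L]
            if (x %in% seen) next
            seen <- c(seen, x)
            nxt <- adj[[x]]
            if (!is.null(nxt)) stack <- c(stack, nxt)
        }
        seen <- setdiff(seen, n)   # A subClassOf A stays implicit
        if (length(seen)) {
            res_sub <- c(res_sub, rep(n, length(seen)))
            res_super <- c(res_super, sort(seen))
        }
    }
    out <- data.frame(sub = res_sub, super = res_super, stringsAsFactors = FALSE)
    out <- out[order(out$sub, out$super), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## canonical orientation per inverse pair: has_result/has_part preferred,
## otherwise the lexicographically smaller id; identity for unpaired
## relations.  Deterministic.
canonicalOrientation <- function(rel) {
    orient <- stats::setNames(rel$id, rel$id)
    pref <- c("has_result", "has_part")
    for (i in seq_len(nrow(rel))) {
        r <- rel$id[i]; iv <- rel$inverse_of[i]
        if (is.na(iv)) next
        pair <- sort(c(r, iv))
        hit <- pair[pair %in% pref]
        orient[pair] <- if (length(hit)) hit[1L] else pair[1L]
    }
    orient
}

#' Materialize the entailed closure of an ontology document
#'
#' Computes the closure of the fragment's completion rules: subsumption
#' transitivity, restriction inheritance down the class hierarchy, filler
#' generalization up the hierarchy, transitive object properties (the
#' causal pair), property chains (\code{has_part_result}) and inverse
#' completion.  Every entailed edge carries a status
#' (\code{asserted}/\code{inferred}) and, for inferred edges, a
#' derivation: the rule tag followed by its premises.
#'
#' @param doc a validated \linkS4class{OntologyDocument}.
#' @return an \linkS4class{InferredGraph}.
#' @examples
#' g <- materialize(senescenceOntology())
#' g
#' @export
materialize <- function(doc) {
    stopifnot(methods::is(doc, "OntologyDocument"))
    rel <- doc@relations
    orient <- canonicalOrientation(rel)
    inv <- stats::setNames(rel$inverse_of, rel$id)
    chain_rel <- rel[!is.na(rel$chain1), , drop = FALSE]
    for (i in seq_len(nrow(chain_rel))) {
        comps <- c(chain_rel$chain1[i], chain_rel$chain2[i])
        miss <- setdiff(comps, rel$id)
        if (length(miss)) {
            stop("chain of relation '", chain_rel$id[i],
                 "' references undeclared relation(s): ",
                 paste(miss, collapse = ", "))
        }
        if (!all(orient[comps] == comps)) {
            stop("chain of relation '", chain_rel$id[i],
                 "' must be stated over canonical orientations (",
                 paste(unique(orient[comps]), collapse = ", "), ")")
        }
    }
    ## a relation is treated as transitive if it or its inverse partner is
    trans <- stats::setNames(rel$transitive, rel$id)
    for (i in seq_len(nrow(rel))) {
        iv <- rel$inverse_of[i]
        if (!is.na(iv) && isTRUE(trans[[iv]])) trans[[rel$id[i]]] <- TRUE
    }

    ax <- doc@axioms
    subs <- subsumptionClosure(ax[ax$kind == "subclass_of", , drop = FALSE])
    subsOf <- split(subs$sub, subs$super)     # class -> its proper subclasses
    supersOf <- split(subs$super, subs$sub)   # class -> its proper superclasses

    status <- new.env(hash = TRUE, parent = emptyenv())
    deriv <- new.env(hash = TRUE, parent = emptyenv())
    outIdx <- new.env(hash = TRUE, parent = emptyenv())  # "s\rr" -> objects
    inIdx <- new.env(hash = TRUE, parent = emptyenv())   # "o\rr" -> subjects

    pending <- list()
    schedule <- function(s, r, o, dv) {
        k <- edgeKey(s, r, o)
        if (!is.null(status[[k]]) || !is.null(pending[[k]])) return(invisible())
        pending[[k]] <<- list(s = s, r = r, o = o, deriv = dv)
        invisible()
    }
    exists_edge <- function(s, r, o) !is.null(status[[edgeKey(s, r, o)]])
    fmt <- function(s, r, o) paste0("[", s, " -", r, "-> ", o, "]")

    ## seed: asserted existential axioms, canonicalized per inverse pair
    ex <- ax[ax$kind == "existential", , drop = FALSE]
    assertedKeys <- character(nrow(ex))
    for (i in seq_len(nrow(ex))) {
        s <- ex$subject[i]; r <- ex$relation[i]; o <- ex$object[i]
        assertedKeys[i] <- edgeKey(s, r, o)
        cr <- if (r %in% names(orient)) orient[[r]] else r
        if (cr == r) {
            schedule(s, r, o, list(paste0("asserted: ", fmt(s, r, o))))
        } else {
            schedule(o, cr, s, list("R6 inverse", paste0("asserted: ", fmt(s, r, o))))
        }
    }
    asserted <- new.env(hash = TRUE, parent = emptyenv())
    for (k in assertedKeys) asserted[[k]] <- TRUE

    while (length(pending)) {
        batch <- pending[order(names(pending))]
        pending <- list()
        for (e in batch) {
            s <- e$s; r <- e$r; o <- e$o
            k <- edgeKey(s, r, o)
            if (!is.null(status[[k]])) next
            status[[k]] <- "canonical"
            deriv[[k]] <- e$deriv
            ko <- paste(s, r, sep = "\r"); ki <- paste(o, r, sep = "\r")
            outIdx[[ko]] <- c(outIdx[[ko]], o)
            inIdx[[ki]] <- c(inIdx[[ki]], s)
            me <- fmt(s, r, o)

            ## R4 transitivity
            if (isTRUE(trans[[r]])) {
                for (o2 in outIdx[[paste(o, r, sep = "\r")]]) {
                    if (!exists_edge(s, r, o2))
                        schedule(s, r, o2,
                                 list("R4 transitivity", me, fmt(o, r, o2)))
                }
                for (s0 in inIdx[[paste(s, r, sep = "\r")]]) {
                    if (!exists_edge(s0, r, o))
                        schedule(s0, r, o,
                                 list("R4 transitivity", fmt(s0, r, s), me))
                }
            }
            ## R5 property chains
            for (ci in seq_len(nrow(chain_rel))) {
                cid <- chain_rel$id[ci]
                c1 <- chain_rel$chain1[ci]; c2 <- chain_rel$chain2[ci]
                if (r == c1) {
                    for (o2 in outIdx[[paste(o, c2, sep = "\r")]]) {
                        if (!exists_edge(s, cid, o2))
                            schedule(s, cid, o2,
                                     list("R5 chain", me, fmt(o, c2, o2)))
                    }
                }
                if (r == c2) {
                    for (s0 in inIdx[[paste(s, c1, sep = "\r")]]) {
                        if (!exists_edge(s0, cid, o))
                            schedule(s0, cid, o,
                                     list("R5 chain", fmt(s0, c1, s), me))
                    }
                }
            }
            ## R2 restriction inheritance (subjects specialize)
            for (a in subsOf[[s]]) {
                if (!exists_edge(a, r, o))
                    schedule(a, r, o,
                             list("R2 inheritance", paste0(a, " subClassOf ", s), me))
            }
            ## R3 filler generalization (objects generalize)
            for (cc in supersOf[[o]]) {
                if (!exists_edge(s, r, cc))
                    schedule(s, r, cc,
                             list("R3 generalization", me, paste0(o, " subClassOf ", cc)))
            }
        }
    }

    ## final pass: R6 inverse completion of the canonical closure
    keys <- sort(ls(status))
    rows <- vector("list", 2L * length(keys))
    n <- 0L
    for (k in keys) {
        parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
        s <- parts[1L]; r <- parts[2L]; o <- parts[3L]
        st <- if (!is.null(asserted[[k]])) "asserted" else "inferred"
        n <- n + 1L
        rows[[n]] <- list(subject = s, relation = r, object = o, status = st,
                          derivation = unlist(deriv[[k]]))
        ri <- inv[[r]]
        if (!is.null(ri) && !is.na(ri)) {
            mk <- edgeKey(o, ri, s)
            mst <- if (!is.null(asserted[[mk]])) "asserted" else "inferred"
            mdv <- if (mst == "asserted") {
                paste0("asserted: ", fmt(o, ri, s))
            } else {
                c("R6 inverse", fmt(s, r, o))
            }
            n <- n + 1L
            rows[[n]] <- list(subject = o, relation = ri, object = s,
                              status = mst, derivation = mdv)
        }
    }
    rows <- rows[seq_len(n)]
    edges <- data.frame(
        subject = vapply(rows, `[[`, character(1), "subject"),
        relation = vapply(rows, `[[`, character(1), "relation"),
        object = vapply(rows, `[[`, character(1), "object"),
        status = vapply(rows, `[[`, character(1), "status"),
        stringsAsFactors = FALSE)
    edges$derivation <- I(lapply(rows, `[[`, "derivation"))
    ord <- order(edges$subject, edges$relation, edges$object)
    edges <- edges[ord, , drop = FALSE]
    dup <- duplicated(paste(edges$subject, edges$relation, edges$object,
                            sep = "\r"))
    edges <- edges[!dup, , drop = FALSE]
    rownames(edges) <- NULL
    methods::new("InferredGraph", edges = edges, subsumptions = subs, doc = doc)
}

#' Query the closure for an entailed edge
#'
#' Tests whether \code{subject -relation-> object} is entailed by the
#' materialized graph and returns the derivation trace.
#'
#' @param graph an \linkS4class{InferredGraph}.
#' @param subject,object class CURIEs (any accepted spelling).
#' @param relation relation id.
#' @return list with elements \code{entailed} (logical) and
#'   \code{derivation} (character vector; the rule tag and premises of the
#'   first derivation found, or the asserted axiom itself).
#' @examples
#' g <- materialize(senescenceOntology())
#' entails(g, "HOIP:0060431", "has_result", "HOIP:0060427")$entailed
#' @export
entails <- function(graph, subject, relation, object) {
    stopifnot(methods::is(graph, "InferredGraph"))
    subject <- normalizeCurie(subject)
    object <- normalizeCurie(object)
    known <- graph@doc@terms$id
    for (x in c(subject, object)) {
        if (!(x %in% known)) stop("unknown class: ", x)
    }
    e <- graph@edges
    hit <- which(e$subject == subject & e$relation == relation &
                     e$object == object)
    if (length(hit)) {
        list(entailed = TRUE, derivation = unlist(e$derivation[[hit[1L]]]))
    } else {
        list(entailed = FALSE, derivation = character(0))
    }
}
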