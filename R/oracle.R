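#' Brute-force closure (test oracle)
#'
#' A deliberately naive fixpoint: every completion rule is re-applied to
#' every pair of current facts with data.frame joins until nothing
#' changes.  Asserted edges are canonicalized per inverse pair up front
#' and the inverse orientation is completed at the end, mirroring the
#' staged semantics of \code{\link{materialize}} through an independent
#' code path (merge joins over full tables vs. an indexed semi-naive
#' engine).  Exists to cross-check the reasoner on small documents.
#'
#' @param doc an \linkS4class{OntologyDocument}.
#' @param maxClasses refuse documents larger than this (the quadratic
#'   recomputation is only meant for fixtures).
#' @return data.frame (\code{subject}, \code{relation}, \code{object}) of
#'   all entailed existential edges, sorted.
#' @export
bruteForceClosure <- function(doc, maxClasses = 200L) {
    stopifnot(methods::is(doc, "OntologyDocument"))
    if (nrow(doc@terms) > maxClasses) {
        stop("bruteForceClosure is a test oracle; refusing a document with ",
             nrow(doc@terms), " classes (> ", maxClasses, ")")
    }
    rel <- doc@relations
    ax <- doc@axioms
    subs <- unique(ax[ax$kind == "subclass_of", c("subject", "object")])
    names(subs) <- c("sub", "super")

    dedupe <- function(df) unique(df[stats::complete.cases(df), , drop = FALSE])

    ## R1: transitive closure of subsumptions by repeated self-join
    repeat {
        joined <- merge(subs, subs, by.x = "super", by.y = "sub")
        if (nrow(joined)) {
            new <- data.frame(sub = joined$sub, super = joined$super.y,
                              stringsAsFactors = FALSE)
            new <- new[new$sub != new$super, , drop = FALSE]
        } else new <- subs[0, ]
        grown <- dedupe(rbind(subs, new))
        if (nrow(grown) == nrow(subs)) break
        subs <- grown
    }

    ## canonicalize asserted edges per inverse pair
    invmap <- stats::setNames(rel$inverse_of, rel$id)
    canon <- stats::setNames(rel$id, rel$id)
    for (i in seq_len(nrow(rel))) {
        iv <- rel$inverse_of[i]
        if (is.na(iv)) next
        pair <- sort(c(rel$id[i], iv))
        hit <- pair[pair %in% c("has_result", "has_part")]
        canon[pair] <- if (length(hit)) hit[1L] else pair[1L]
    }
    edges <- unique(ax[ax$kind == "existential",
                       c("subject", "relation", "object")])
    flip <- !is.na(canon[edges$relation]) & canon[edges$relation] != edges$relation
    edges <- data.frame(
        subject = ifelse(flip, edges$object, edges$subject),
        relation = ifelse(is.na(canon[edges$relation]), edges$relation,
                          canon[edges$relation]),
        object = ifelse(flip, edges$subject, edges$object),
        stringsAsFactors = FALSE)
    edges <- dedupe(edges)

    trans_ids <- rel$id[rel$transitive]
    trans_ids <- unique(canon[trans_ids])
    chain_rel <- rel[!is.na(rel$chain1), c("id", "chain1", "chain2")]

    repeat {
        new <- edges[0, ]
        ## R4 transitivity
        for (r in trans_ids) {
            have <- edges[edges$relation == r, , drop = FALSE]
            if (nrow(have)) {
                j <- merge(have, have, by.x = "object", by.y = "subject")
                if (nrow(j)) {
                    new <- rbind(new, data.frame(subject = j$subject,
                                                 relation = r,
                                                 object = j$object.y,
                                                 stringsAsFactors = FALSE))
                }
            }
        }
        ## R5 chains
        for (i in seq_len(nrow(chain_rel))) {
            e1 <- edges[edges$relation == chain_rel$chain1[i], , drop = FALSE]
            e2 <- edges[edges$relation == chain_rel$chain2[i], , drop = FALSE]
            if (nrow(e1) && nrow(e2)) {
                j <- merge(e1, e2, by.x = "object", by.y = "subject")
                if (nrow(j)) {
                    new <- rbind(new, data.frame(subject = j$subject,
                                                 relation = chain_rel$id[i],
                                                 object = j$object.y,
                                                 stringsAsFactors = FALSE))
                }
            }
        }
        ## R2 restriction inheritance
        j <- merge(subs, edges, by.x = "super", by.y = "subject")
        if (nrow(j)) {
            new <- rbind(new, data.frame(subject = j$sub, relation = j$relation,
                                         object = j$object,
                                         stringsAsFactors = FALSE))
        }
        ## R3 filler generalization
        j <- merge(edges, subs, by.x = "object", by.y = "sub")
        if (nrow(j)) {
            new <- rbind(new, data.frame(subject = j$subject,
                                         relation = j$relation,
                                         object = j$super,
                                         stringsAsFactors = FALSE))
        }
        grown <- dedupe(rbind(edges, new))
        if (nrow(grown) == nrow(edges)) break
        edges <- grown
    }

    ## R6: inverse completion of the canonical closure
    paired <- edges[!is.na(invmap[edges$relation]), , drop = FALSE]
    if (nrow(paired)) {
        mirrors <- data.frame(subject = paired$object,
                              relation = unname(invmap[paired$relation]),
                              object = paired$subject,
                              stringsAsFactors = FALSE)
        edges <- dedupe(rbind(edges, mirrors))
    }
    edges <- edges[order(edges$subject, edges$relation, edges$object), ,
                   drop = FALSE]
    rownames(edges) <- NULL
    edges
}
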