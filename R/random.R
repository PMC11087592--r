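## Seeded random ontologies with an independently computed ground-truth
## closure, for property-based testing of the reasoners.

## boolean-matrix transitive closure (Warshall)
boolClosure <- function(M) {
    n <- nrow(M)
    for (k in seq_len(n)) {
        hit <- which(M[, k])
        if (length(hit)) M[hit, ] <- M[hit, , drop = FALSE] | rep(M[k, ], each = length(hit))
    }
    M
}

matToTriples <- function(M, relation, ids) {
    w <- which(M, arr.ind = TRUE)
    if (nrow(w) == 0L) {
        return(data.frame(subject = character(0), relation = character(0),
                          object = character(0), stringsAsFactors = FALSE))
    }
    data.frame(subject = ids[w[, 1L]], relation = relation,
               object = ids[w[, 2L]], stringsAsFactors = FALSE)
}

#' Random ontology with a known closure
#'
#' Generates a seeded random document over the canonical relation
#' registry: a subclass forest, a causal DAG (some edges asserted in the
#' inverse \code{has_cause} orientation, optionally with injected cycle
#' back-edges), and part-whole edges whose density controls how many
#' \code{has_part_result} chain entailments arise.  The ground-truth
#' closure is computed constructively by boolean linear algebra
#' (lift-along-hierarchy sandwich products and Warshall closure), a third
#' code path independent of both \code{\link{materialize}} and
#' \code{\link{bruteForceClosure}}.
#'
#' @param nClasses number of classes (>= 2).
#' @param maxOutDegree maximum asserted causal out-degree per class.
#' @param chainDensity probability in [0, 1] that a class carries a
#'   \code{has_part} edge (0 means no chain entailments).
#' @param specializationRate probability in [0, 1] that a class gets a
#'   superclass.
#' @param seed integer seed; same seed, same output.
#' @param cycles number of extra back-edges injected to create causal
#'   cycles.
#' @return list with \code{document} (an \linkS4class{OntologyDocument})
#'   and \code{closure} (data.frame \code{subject}, \code{relation},
#'   \code{object}: the expected entailed edge set).
#' @export
randomOntology <- function(nClasses = 30L, maxOutDegree = 3L,
                           chainDensity = 0.3, specializationRate = 0.2,
                           seed = 1L, cycles = 0L) {
    if (nClasses < 2L || maxOutDegree < 0L || cycles < 0L) {
        stop("degenerate fixture parameters: nClasses >= 2, ",
             "maxOutDegree >= 0, cycles >= 0 required")
    }
    if (chainDensity < 0 || chainDensity > 1 ||
        specializationRate < 0 || specializationRate > 1) {
        stop("degenerate fixture parameters: densities must lie in [0, 1]")
    }
    set.seed(as.integer(seed))
    n <- as.integer(nClasses)
    ids <- sprintf("RND:%07d", seq_len(n))
    ## length-safe sampler (sample() treats a scalar as 1:x)
    resample <- function(x, k) x[sample.int(length(x), k)]

    S <- matrix(FALSE, n, n)   # sub -> super
    for (i in 2:n) {
        if (stats::runif(1) < specializationRate) {
            S[i, sample.int(i - 1L, 1L)] <- TRUE
        }
    }
    Er <- matrix(FALSE, n, n)  # asserted causal edges (result orientation)
    flipCause <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) {
        k <- sample.int(maxOutDegree + 1L, 1L) - 1L
        if (k == 0L) next
        targets <- resample((i + 1L):n, min(k, n - i))
        Er[i, targets] <- TRUE
        ## some edges are asserted in the inverse (has_cause) orientation
        flipCause[i, targets] <- stats::runif(length(targets)) < 0.25
    }
    if (cycles > 0L) {
        for (b in seq_len(cycles)) {
            j <- resample(2:n, 1L); i <- sample.int(j - 1L, 1L)
            Er[j, i] <- TRUE    # back-edge i <- j closes a cycle
        }
    }
    Ep <- matrix(FALSE, n, n)  # asserted has_part edges
    flipPart <- matrix(FALSE, n, n)
    for (i in seq_len(n)) {
        if (stats::runif(1) < chainDensity) {
            j <- resample(setdiff(seq_len(n), i), 1L)
            Ep[i, j] <- TRUE
            flipPart[i, j] <- stats::runif(1) < 0.25
        }
    }

    axioms <- emptyAxiomTable()
    w <- which(S, arr.ind = TRUE)
    for (r in seq_len(nrow(w))) {
        axioms <- rbind(axioms, ax_sub(ids[w[r, 1L]], ids[w[r, 2L]],
                                       provenance = "fixture"))
    }
    w <- which(Er, arr.ind = TRUE)
    for (r in seq_len(nrow(w))) {
        i <- w[r, 1L]; j <- w[r, 2L]
        axioms <- rbind(axioms, if (flipCause[i, j]) {
            ax_ex(ids[j], "has_cause", ids[i], provenance = "fixture")
        } else {
            ax_ex(ids[i], "has_result", ids[j], provenance = "fixture")
        })
    }
    w <- which(Ep, arr.ind = TRUE)
    for (r in seq_len(nrow(w))) {
        i <- w[r, 1L]; j <- w[r, 2L]
        axioms <- rbind(axioms, if (flipPart[i, j]) {
            ax_ex(ids[j], "part_of", ids[i], provenance = "fixture")
        } else {
            ax_ex(ids[i], "has_part", ids[j], provenance = "fixture")
        })
    }

    doc <- makeOntologyDocument(
        terms = data.frame(id = ids, label = paste("random process", seq_len(n)),
                           entity_kind = "process", stringsAsFactors = FALSE),
        relations = canonicalRelationRegistry(),
        axioms = axioms,
        metadata = list(source = "randomOntology", seed = as.integer(seed)))

    ## ground truth by linear algebra: Seps = reflexive-transitive
    ## subsumption; lift = Seps %*% E %*% Seps (inheritance down the
    ## subject, generalization up the filler); Warshall for transitivity.
    Seps <- boolClosure(S); diag(Seps) <- TRUE
    bmm <- function(A, B) (A %*% B) > 0
    Lr <- bmm(bmm(Seps, Er), Seps)
    Tr <- boolClosure(Lr)
    Lp <- bmm(bmm(Seps, Ep), Seps)
    Cpr <- bmm(Lp, Tr)          # has_part o has_result => has_part_result
    closure <- rbind(matToTriples(Tr, "has_result", ids),
                     matToTriples(t(Tr), "has_cause", ids),
                     matToTriples(Lp, "has_part", ids),
                     matToTriples(t(Lp), "part_of", ids),
                     matToTriples(Cpr, "has_part_result", ids))
    closure <- closure[order(closure$subject, closure$relation,
                             closure$object), , drop = FALSE]
    rownames(closure) <- NULL
    list(document = doc, closure = closure)
}
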