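#' Normalize compact identifiers (CURIEs)
#'
#' Ontology sources mix several spellings of the same identifier:
#' underscore form (\code{"HOIP_0060024"}), colon form
#' (\code{"HOIP:0060102"}), BioPortal class URIs
#' (\code{"http://purl.bioontology.org/ontology/HOIP/HOIP0060144"}) and OBO
#' PURLs (\code{".../obo/PR_P20700"}).  \code{normalizeCurie} maps all of
#' them to the canonical colon form \code{"PREFIX:LOCALID"}; equality of
#' identifiers throughout the package is equality of normalized forms.
#'
#' The function is idempotent: applying it to an already-normalized CURIE
#' returns the input unchanged.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of normalized CURIEs.
#' @examples
#' normalizeCurie("HOIP_0060024")
#' normalizeCurie("http://purl.bioontology.org/ontology/HOIP/HOIP0060144")
#' @export
normalizeCurie <- function(x) {
    if (length(x) == 0L) return(character(0))
    stopifnot(is.character(x))
    vapply(x, normalizeCurie1, character(1), USE.NAMES = FALSE)
}

normalizeCurie1 <- function(raw) {
    if (is.na(raw) || !nzchar(raw)) {
        stop("cannot parse CURIE from empty or missing input")
    }
    s <- trimws(raw)
    ## full URIs: BioPortal pattern .../HOIP/HOIP0060144 or OBO .../PR_P20700
    if (grepl("^https?://", s)) {
        local <- sub("^.*[/#]", "", s)
        if (grepl("^[A-Za-z][A-Za-z0-9]*_[A-Za-z0-9]+$", local)) {
            parts <- strsplit(local, "_", fixed = TRUE)[[1]]
            return(paste0(parts[1], ":", paste(parts[-1], collapse = "_")))
        }
        ## BioPortal style: prefix repeated and glued to the local id
        m <- regmatches(local, regexec("^([A-Za-z]+)([0-9][A-Za-z0-9]*)$", local))[[1]]
        if (length(m) == 3L) return(paste0(m[2], ":", m[3]))
        stop("cannot parse CURIE from URI: ", raw)
    }
    if (grepl("^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9_.-]+$", s)) return(s)
    if (grepl("^[A-Za-z][A-Za-z0-9]*_[A-Za-z0-9_.-]+$", s)) {
        i <- regexpr("_", s, fixed = TRUE)
        return(paste0(substr(s, 1L, i - 1L), ":",
                      substr(s, i + 1L, nchar(s))))
    }
    stop("cannot parse CURIE: ", raw)
}

curiePrefix <- function(x) sub(":.*$", "", normalizeCurie(x))

curieLocal <- function(x) sub("^[^:]*:", "", normalizeCurie(x))

#' Resolve a CURIE to its public URI
#'
#' HOIP classes live under the BioPortal ontology namespace
#' (\code{http://purl.bioontology.org/ontology/HOIP/HOIP0060102}); classes
#' imported from OBO Foundry ontologies (PR, CHEBI, DOID, SYMP, GO, ...)
#' resolve to OBO PURLs.
#'
#' @param x character vector of CURIEs (any accepted spelling).
#' @return character vector of URIs.
#' @examples
#' curieToURI("HOIP:0060102")
#' curieToURI("PR:P20700")
#' @export
curieToURI <- function(x) {
    x <- normalizeCurie(x)
    pre <- curiePrefix(x)
    loc <- curieLocal(x)
    ifelse(pre == "HOIP",
           paste0("http://purl.bioontology.org/ontology/HOIP/HOIP", loc),
           paste0("http://purl.obolibrary.org/obo/", pre, "_", loc))
}
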