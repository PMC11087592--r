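#' Canonical object-property registry
#'
#' The fixed set of object properties used by homeostasis-imbalance process
#' ontologies, with their logical characteristics:
#' \itemize{
#'   \item \code{has_part} / \code{part_of}: mutually inverse whole-part
#'     relations between a course (or process) and its constituent
#'     processes; not transitive by default (configurable via
#'     \code{partTransitive}).
#'   \item \code{has_result} / \code{has_cause}: mutually inverse causal
#'     relations between processes; both transitive, so reasoning yields
#'     indirect as well as direct causes.
#'   \item \code{has_part_result}: defined by the property chain
#'     \code{has_part o has_result}, connecting a whole process to the
#'     results of its parts.
#'   \item \code{has_output}: process to the material entity it produces.
#'   \item \code{has_role}: molecule to its contextual role (range: role),
#'     e.g. the SASP-factor role.
#'   \item \code{occurs_in}: process to its location.
#'   \item \code{manifests_symptom}: process to a clinical symptom (range:
#'     symptom).
#'   \item \code{realizes_disease}: process to the disease it realizes
#'     (domain: process, range: disease).
#' }
#'
#' @param partTransitive should \code{has_part}/\code{part_of} be treated
#'   as transitive?  Default \code{FALSE}: only the causal pair is.
#' @return data.frame in the relation-table layout of
#'   \linkS4class{OntologyDocument}.
#' @examples
#' reg <- canonicalRelationRegistry()
#' reg[reg$id == "has_result", "transitive"]
#' @export
canonicalRelationRegistry <- function(partTransitive = FALSE) {
    r <- function(id, label, transitive = FALSE, inverse_of = NA_character_,
                  chain1 = NA_character_, chain2 = NA_character_,
                  domain_kind = NA_character_, range_kind = NA_character_) {
        data.frame(id = id, label = label, transitive = transitive,
                   inverse_of = inverse_of, chain1 = chain1, chain2 = chain2,
                   domain_kind = domain_kind, range_kind = range_kind,
                   stringsAsFactors = FALSE)
    }
    rbind(
        r("has_part", "has part", transitive = partTransitive,
          inverse_of = "part_of"),
        r("part_of", "part of", transitive = partTransitive,
          inverse_of = "has_part"),
        r("has_result", "has result", transitive = TRUE,
          inverse_of = "has_cause"),
        r("has_cause", "has cause", transitive = TRUE,
          inverse_of = "has_result"),
        r("has_part_result", "has part result",
          chain1 = "has_part", chain2 = "has_result"),
        r("has_output", "has output"),
        r("has_role", "has role", range_kind = "role"),
        r("occurs_in", "occurs in"),
        r("manifests_symptom", "manifests symptom", range_kind = "symptom"),
        r("realizes_disease", "realizes disease",
          domain_kind = "process", range_kind = "disease")
    )
}
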