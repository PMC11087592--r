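## Curated cellular-senescence demonstration ontology.
##
## Encodes the published course taxonomy and causal structure of the
## cellular-senescence knowledge model: the course hierarchy with its
## textual definitions, the per-course p21 signaling chains, DDR with its
## ATM/ATR sub-processes, SASP secretion with its outputs/roles/location,
## the type-2-diabetes causal chain, the LMNB1/cGAS-STING chain, the
## cross-course IL-6/IL-8 structure shared with the COVID-19 courses, the
## senolytics (metformin/NFKB) branch with negation-marked processes, and
## the four-stage homeostatic-imbalance tags.
##
## Identifiers in the HOIP:0099*** range are synthetic placeholders minted
## by this package for entities that the source knowledge model names in
## prose without a stable published identifier (including the COVID course
## classes used for the cross-course examples); all other identifiers are
## the published ones.

#' Curated cellular-senescence ontology
#'
#' Builds the demonstration \linkS4class{OntologyDocument}: seven
#' senescence-related courses (root, embryonic, adult, acute, chronic,
#' chronic-with-type-2-diabetes, senolytics) plus two COVID-19 courses for
#' cross-course inference, their member processes, causal edges,
#' molecule/role/disease/symptom attachments and homeostatic-imbalance
#' stage tags.  Pure and deterministic: two calls return identical
#' documents.
#'
#' @return an \linkS4class{OntologyDocument} that passes
#'   \code{\link{validateDocument}} with zero violations.
#' @examples
#' doc <- senescenceOntology()
#' doc
#' @export
senescenceOntology <- function() {
    trm <- function(id, label, kind = "process", def = NA_character_,
                    desc = NA_character_, xrefs = NA_character_,
                    negated = FALSE, taxon = NA_character_,
                    stage = NA_character_, equiv = NA_character_) {
        data.frame(id = id, label = label, entity_kind = kind,
                   definition = def, description = desc, xrefs = xrefs,
                   negated = negated, taxon = taxon, stage = stage,
                   equivalent_to = equiv, stringsAsFactors = FALSE)
    }
    HS <- "NCBITaxon:9606"

    terms <- rbind(
        ## --- courses -----------------------------------------------------
        trm("HOIP:0099001", "homeostatic imbalance course", "course",
            def = "A process sequence consisting of multiple processes through which a homeostatic imbalance unfolds."),
        trm("HOIP:0060024", "cellular senescence course", "course",
            def = "A course constituting multiple processes that lead to cellular senescence."),
        trm("HOIP:0060267", "embryonic cellular senescence course", "course",
            def = "A cellular senescence course that occurs during embryogenesis.",
            equiv = "HOIP:00600267"),
        trm("HOIP:00600267", "embryonic cellular senescence course (variant identifier)",
            "course",
            desc = "Duplicate identifier recorded for the embryonic course; cross-linked to the canonical HOIP:0060267.",
            equiv = "HOIP:0060267"),
        trm("HOIP:0060315", "adult cellular senescence course", "course",
            def = "A cellular senescence course in adults."),
        trm("HOIP:0060196", "acute cellular senescence course", "course",
            def = "An adult cellular senescence course that can cause transient cellular senescence."),
        trm("HOIP:0060195", "chronic cellular senescence course", "course",
            def = "An adult cellular senescence course that can result in a sustained cellular senescence process, which may lead to the senescence-associated secretory phenotype (SASP), and chronic inflammation due to senescent cell accumulation."),
        trm("HOIP:0060423", "chronic cellular senescence course associated with type 2 diabetes mellitus",
            "course",
            def = "A chronic cellular senescence course associated with type 2 diabetes mellitus."),
        trm("HOIP:0060418", "senolytics course", "course",
            def = "A chronic cellular senescence course modulated by senolytic intervention."),
        trm("HOIP:0099100", "COVID-19 infectious course", "course",
            def = "A homeostatic imbalance course triggered by SARS-CoV-2 infection."),
        trm("HOIP:0099101", "COVID-19 associated with ARDS course", "course"),
        trm("HOIP:0099102", "severe COVID-19 course", "course"),
        ## --- upper process classes --------------------------------------
        trm("GO:0008150", "biological process"),
        trm("GO:0045087", "innate immune response"),
        trm("GO:0006954", "inflammatory response"),
        trm("HOIP:0004327", "IL-6 signaling"),
        trm("HOIP:0041903", "CXCL8 (IL-8) signaling"),
        ## --- core senescence processes ----------------------------------
        trm("HOIP:0060129", "cellular senescence",
            def = "A cell aging process stimulated in response to cellular stress, whereby normal cells lose the ability to divide through irreversible cell cycle arrest."),
        trm("HOIP:0099002", "transient cellular senescence", stage = "outcome"),
        trm("HOIP:0060240", "cellular senescence (sustained)", stage = "outcome"),
        trm("HOIP:0060110", "ATM signaling"),
        trm("HOIP:0060140", "ATR signaling"),
        trm("HOIP:0060337", "DDR signaling", stage = "stress_response",
            desc = "DNA damage response signaling in which ATM or ATR kinases block cell-cycle progression through stabilization of p53 and transcriptional activation of p21."),
        trm("HOIP:0060144", "CHK1 signaling [adult cellular senescence]",
            xrefs = "PMID:33328614"),
        trm("HOIP:0060055", "p53 signaling [adult cellular senescence]",
            equiv = "HOIP:0060321"),
        trm("HOIP:0099003", "regulation of gene expression by p53"),
        trm("HOIP:0060325", "p21 signaling"),
        ## --- embryonic course -------------------------------------------
        trm("HOIP:0099004", "increasing demand for pattern specification",
            stage = "stress_demand"),
        trm("HOIP:0060269", "TGF beta signaling", stage = "stress_response"),
        trm("HOIP:0060290", "SMAD signaling"),
        trm("HOIP:0099005", "regulation of gene expression by SMAD"),
        trm("HOIP:0099006", "homeostatic imbalance between pattern-specification demand and stress response",
            stage = "imbalance"),
        trm("HOIP:0099007", "tissue remodelling"),
        trm("HOIP:0099008", "embryonic pattern specification"),
        ## --- acute course ------------------------------------------------
        trm("HOIP:0099009", "increasing demand for the oncogenic stress response",
            stage = "stress_demand"),
        trm("HOIP:0099010", "PTEN loss"),
        trm("HOIP:0099011", "homeostatic imbalance between oncogenic stress and defence response",
            stage = "imbalance"),
        trm("HOIP:0099012", "negative regulation of tumour proliferation"),
        ## --- chronic course ----------------------------------------------
        trm("HOIP:0060431", "telomere shortening", stage = "stress_demand"),
        trm("HOIP:0060321", "p53 signaling [chronic cellular senescence]",
            stage = "stress_response", equiv = "HOIP:0060055"),
        trm("HOIP:0060294", "p16 signaling"),
        trm("HOIP:0060162", "senescence-associated heterochromatin focus formation"),
        trm("HOIP:0099013", "homeostatic imbalance between chronic stress and stress response",
            stage = "imbalance"),
        trm("HOIP:0060308", "accumulation of senescent cells (sustained)"),
        trm("HOIP:0060102", "SASP secretion",
            def = "Secretion of senescence-associated secretory phenotype factors, such as interleukin-6 and interleukin-8, by senescent cells."),
        trm("HOIP:0060113", "chronic inflammation"),
        trm("HOIP:0060112", "fibrosis"),
        trm("HOIP:0060182", "negative regulation of tissue regeneration"),
        trm("HOIP:0060639", "IL-6 signaling [chronic cellular senescence]",
            equiv = "HOIP:0004327"),
        trm("HOIP:0060640", "CXCL8 (IL-8) signaling [chronic cellular senescence]"),
        trm("HOIP:0099014", "NFKB signaling [chronic cellular senescence]"),
        trm("HOIP:0060132", "LMNB1 degradation in lysosome"),
        trm("HOIP:0060190", "release of cytosolic chromatin fragments"),
        trm("HOIP:0060172", "cGAS signaling"),
        trm("HOIP:0060179", "STING signaling"),
        trm("HOIP:0060183", "IRF activation"),
        ## --- type 2 diabetes course --------------------------------------
        trm("HOIP:0060427", "insulin resistance"),
        trm("HOIP:0060453", "type B pancreatic cell exhaustion/hypofunction"),
        trm("HOIP:0060455", "positive regulation of SASP secretion"),
        trm("HOIP:0060432", "SASP secretion [type 2 diabetes mellitus]"),
        trm("HOIP:0060504", "FOXO signaling"),
        trm("HOIP:0060512", "TLR4 signaling"),
        trm("HOIP:0060496", "increasing urine production"),
        ## --- senolytics course -------------------------------------------
        trm("HOIP:0060417", "negative regulation of NFKB signaling",
            desc = "Down-regulation of NFKB signaling by senolytic drugs such as metformin (CHEBI:6801).",
            xrefs = "CHEBI:6801"),
        trm("HOIP:0099015", "no NFKB signaling", negated = TRUE),
        trm("HOIP:0099016", "no SASP secretion", negated = TRUE),
        ## --- COVID-19 processes ------------------------------------------
        trm("HOIP:0099110", "CXCL8 (IL-8) signaling [COVID-19 associated with ARDS]"),
        trm("HOIP:0099111", "CXCL8 (IL-8) signaling [severe COVID-19]"),
        trm("HOIP:0099116", "neutrophil extracellular trap formation/NETosis"),
        trm("HOIP:0099112", "NETosis"),
        trm("HOIP:0099113", "neutrophil extracellular trap formation"),
        trm("HOIP:0041811", "thrombus formation in the lung (very high) [COVID-19 associated with ARDS]"),
        trm("HOIP:0039281", "microvascular dysfunction [severe COVID-19]"),
        trm("HOIP:0099115", "pulmonary inflammation [COVID-19]"),
        ## --- molecules, roles, locations, disease, symptom ---------------
        trm("PR:P20700", "lamin-B1 (human)", "material_entity", taxon = HS),
        trm("PR:P05231", "interleukin-6 (human)", "material_entity", taxon = HS),
        trm("PR:P10145", "interleukin-8 (human)", "material_entity", taxon = HS),
        trm("CHEBI:6801", "metformin", "material_entity"),
        trm("HOIP:0099020", "SASP factor", "role"),
        trm("HOIP:0099021", "senescent cell", "anatomical_entity"),
        trm("DOID:9352", "type 2 diabetes mellitus", "disease"),
        trm("SYMP:0000565", "polyuria", "symptom"))

    sub <- function(s, o) ax_sub(s, o, provenance = "fixture")
    part <- function(course, members) {
        do.call(rbind, lapply(members, function(m)
            ax_ex(course, "has_part", m, provenance = "fixture")))
    }
    res <- function(chain) {
        do.call(rbind, lapply(seq_len(length(chain) - 1L), function(i)
            ax_ex(chain[i], "has_result", chain[i + 1L],
                  provenance = "fixture")))
    }
    ex <- function(s, r, o) ax_ex(s, r, o, provenance = "fixture")

    axioms <- rbind(
        ## course hierarchy
        sub("HOIP:0060024", "HOIP:0099001"),
        sub("HOIP:0060267", "HOIP:0060024"),
        sub("HOIP:00600267", "HOIP:0060024"),
        sub("HOIP:0060315", "HOIP:0060024"),
        sub("HOIP:0060196", "HOIP:0060315"),
        sub("HOIP:0060195", "HOIP:0060315"),
        sub("HOIP:0060423", "HOIP:0060195"),
        sub("HOIP:0060418", "HOIP:0060195"),
        sub("HOIP:0099100", "HOIP:0099001"),
        sub("HOIP:0099101", "HOIP:0099100"),
        sub("HOIP:0099102", "HOIP:0099100"),
        ## process hierarchy
        sub("GO:0045087", "GO:0008150"),
        sub("GO:0006954", "GO:0008150"),
        sub("HOIP:0004327", "GO:0045087"),
        sub("HOIP:0041903", "GO:0045087"),
        sub("HOIP:0099002", "HOIP:0060129"),
        sub("HOIP:0060240", "HOIP:0060129"),
        sub("HOIP:0060113", "GO:0006954"),
        sub("HOIP:0099115", "GO:0006954"),
        sub("HOIP:0060639", "HOIP:0004327"),
        sub("HOIP:0060640", "HOIP:0041903"),
        sub("HOIP:0099110", "HOIP:0041903"),
        sub("HOIP:0099111", "HOIP:0041903"),
        sub("HOIP:0099014", "GO:0045087"),
        sub("HOIP:0060172", "GO:0045087"),
        sub("HOIP:0060179", "GO:0045087"),
        sub("HOIP:0099116", "GO:0045087"),
        sub("HOIP:0099112", "HOIP:0099116"),
        sub("HOIP:0099113", "HOIP:0099116"),
        sub("HOIP:0060432", "HOIP:0060102"),
        ## course membership
        part("HOIP:0060024", "HOIP:0060129"),
        part("HOIP:0060267", c("HOIP:0099004", "HOIP:0060269", "HOIP:0060290",
                               "HOIP:0099005", "HOIP:0060325", "HOIP:0099006",
                               "HOIP:0099002", "HOIP:0099007", "HOIP:0099008")),
        part("HOIP:0060315", c("HOIP:0060337", "HOIP:0060110", "HOIP:0060140",
                               "HOIP:0060144", "HOIP:0060055", "HOIP:0099003",
                               "HOIP:0060325")),
        part("HOIP:0060196", c("HOIP:0099009", "HOIP:0099010", "HOIP:0099011",
                               "HOIP:0099002", "HOIP:0099012")),
        part("HOIP:0060195", c("HOIP:0060240", "HOIP:0060308", "HOIP:0060113",
                               "HOIP:0060431", "HOIP:0060294", "HOIP:0060321",
                               "HOIP:0060162", "HOIP:0060102", "HOIP:0060112",
                               "HOIP:0060182", "HOIP:0060639", "HOIP:0060640",
                               "HOIP:0099014", "HOIP:0060132", "HOIP:0060190",
                               "HOIP:0060172", "HOIP:0060179", "HOIP:0060183",
                               "HOIP:0099013")),
        part("HOIP:0060423", c("HOIP:0060427", "HOIP:0060453", "HOIP:0060455",
                               "HOIP:0060432", "HOIP:0060504", "HOIP:0060512",
                               "HOIP:0060496")),
        part("HOIP:0060418", c("HOIP:0060417", "HOIP:0099015", "HOIP:0099016")),
        part("HOIP:0099101", c("HOIP:0099110", "HOIP:0099112", "HOIP:0099113",
                               "HOIP:0041811", "HOIP:0099115")),
        part("HOIP:0099102", c("HOIP:0099111", "HOIP:0039281")),
        ## process part-whole structure
        ex("HOIP:0060337", "has_part", "HOIP:0060140"),
        ex("HOIP:0060337", "has_part", "HOIP:0060110"),
        ex("HOIP:0060102", "has_part", "HOIP:0060639"),
        ex("HOIP:0060102", "has_part", "HOIP:0060640"),
        ex("HOIP:0099009", "has_part", "HOIP:0099010"),
        ## adult p21 chain
        res(c("HOIP:0060110", "HOIP:0060055", "HOIP:0099003", "HOIP:0060325")),
        ex("HOIP:0060140", "has_result", "HOIP:0060055"),
        ## embryonic p21 chain and outcome chain
        res(c("HOIP:0099004", "HOIP:0060269", "HOIP:0060290", "HOIP:0099005",
              "HOIP:0060325", "HOIP:0099006", "HOIP:0099002", "HOIP:0099007",
              "HOIP:0099008")),
        ## acute course chain
        res(c("HOIP:0099009", "HOIP:0060337", "HOIP:0099011", "HOIP:0099002")),
        ex("HOIP:0099002", "has_result", "HOIP:0099012"),
        ## chronic course chain
        res(c("HOIP:0060431", "HOIP:0060321", "HOIP:0099013", "HOIP:0060240",
              "HOIP:0060308", "HOIP:0060102")),
        ex("HOIP:0060240", "has_result", "HOIP:0060162"),
        ex("HOIP:0060294", "has_result", "HOIP:0060240"),
        ex("HOIP:0060102", "has_result", "HOIP:0060113"),
        ex("HOIP:0060102", "has_result", "HOIP:0060112"),
        ex("HOIP:0060102", "has_result", "HOIP:0060182"),
        ex("HOIP:0060639", "has_result", "HOIP:0060113"),
        ex("HOIP:0060640", "has_result", "HOIP:0060113"),
        ex("HOIP:0060179", "has_result", "HOIP:0099014"),
        ex("HOIP:0099014", "has_result", "HOIP:0060640"),
        ## LMNB1 / cGAS-STING chain
        res(c("HOIP:0060132", "HOIP:0060190", "HOIP:0060172", "HOIP:0060179",
              "HOIP:0060183")),
        ex("HOIP:0060431", "has_result", "HOIP:0060190"),
        ## SASP secretion attachments
        ex("HOIP:0060102", "has_output", "PR:P05231"),
        ex("HOIP:0060102", "has_output", "PR:P10145"),
        ex("HOIP:0060102", "has_role", "HOIP:0099020"),
        ex("HOIP:0060102", "occurs_in", "HOIP:0099021"),
        ex("HOIP:0060132", "has_output", "PR:P20700"),
        ## type 2 diabetes chain
        res(c("HOIP:0060431", "HOIP:0060453", "HOIP:0060455", "HOIP:0060432",
              "HOIP:0060427", "HOIP:0060496")),
        ex("HOIP:0060504", "has_result", "HOIP:0060427"),
        ex("HOIP:0060512", "has_result", "HOIP:0060427"),
        ex("HOIP:0060427", "realizes_disease", "DOID:9352"),
        ex("HOIP:0060496", "manifests_symptom", "SYMP:0000565"),
        ## senolytics chain (negation-marked downstream)
        res(c("HOIP:0060417", "HOIP:0099015", "HOIP:0099016")),
        ## COVID-19 cross-course structure
        ex("HOIP:0099110", "has_result", "HOIP:0099112"),
        ex("HOIP:0099110", "has_result", "HOIP:0099113"),
        ex("HOIP:0099112", "has_result", "HOIP:0041811"),
        ex("HOIP:0099113", "has_result", "HOIP:0041811"),
        ex("HOIP:0099110", "has_result", "HOIP:0099115"),
        ex("HOIP:0099111", "has_result", "HOIP:0039281"))

    makeOntologyDocument(
        terms = terms,
        relations = canonicalRelationRegistry(),
        axioms = axioms,
        metadata = list(iri = "https://w3id.org/hoipr/ontology/senescence",
                        version = "0.99.0",
                        source = "curated cellular-senescence knowledge model",
                        roots = c("HOIP:0099001", "GO:0008150")))
}
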