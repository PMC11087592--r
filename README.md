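# hoipr — homeostasis-imbalance process ontologies for cellular senescence

Cellular senescence — stable proliferative arrest of a cell under stress —
is a driver of organismal aging with both protective (embryonic patterning,
tumour suppression) and harmful (chronic inflammation, type 2 diabetes)
faces.  Knowledge about its mechanisms is scattered across textbooks and
reviews; ontology engineering turns it into a computable causal model.
`hoipr` is an R toolkit for such models: homeostasis-imbalance process
ontologies, in which a *course* (a process sequence such as "chronic
cellular senescence course") is composed of processes via `has part`,
processes are linked by a transitive causal relation `has result` (inverse
`has cause`), and molecules, roles, locations, symptoms and diseases hang
off processes via dedicated object properties.  It is aimed at
computational biologists and biomedical ontologists who want to query and
visualize such causal knowledge without running an OWL reasoner stack.

## The model and reasoner

Documents are restricted to an OWL-DL fragment: named-class subsumption
`A ⊑ B` and existential restrictions `A ⊑ ∃R.B`, read as typed class-level
edges `A -R→ B`.  The materializing reasoner computes the least closure
under:

* **R1** subsumption transitivity: `A ⊑ B, B ⊑ C ⇒ A ⊑ C`
* **R2** restriction inheritance: `A ⊑ B, B -R→ C ⇒ A -R→ C`
* **R3** filler generalization: `A -R→ B, B ⊑ C ⇒ A -R→ C`
* **R4** transitive relations: `A -R→ B -R→ C ⇒ A -R→ C` (the causal pair)
* **R5** property chains: `has_part ∘ has_result ⊑ has_part_result`
* **R6** inverse completion: `A -R→ B ⇔ B -R⁻→ A`

R2–R5 run on a canonical orientation per inverse pair and R6 completes the
mirror image, so causes and results always agree while restrictions
propagate only subject-down / filler-up.  A deliberately naive brute-force
fixpoint (`bruteForceClosure`) and a boolean-linear-algebra ground truth in
the random-ontology generator serve as independent cross-checks.

On top of the closure sit course-scoped queries (`courseMembers` with
inheritance and specialization, `causesOf`, `resultsOf`, `causalPaths`,
`crossCourseResults`, `commonGeneralizedProcesses`,
`generalizedCausalNetwork`), a checker for the four-stage
homeostatic-imbalance pattern (stress demand → stress response → imbalance
→ outcome; `checkCoursePattern`), Turtle/RDF-XML I/O (`readOntology`,
`writeOntology`) and styled network exporters (`toSIF`, `toGraphML`,
`toCX`, `nodeTable`).

## Worked example

```r
library(hoipr)

doc <- senescenceOntology()         # curated demonstration ontology
graph <- materialize(doc)
graph
#> InferredGraph: 120 asserted + 928 inferred edges; 65 subsumption pairs

## what can cause insulin resistance within the diabetes-associated course?
causesOf(graph, "HOIP:0060427", course = "HOIP:0060423")
#> [1] "HOIP:0060431" "HOIP:0060432" "HOIP:0060453" "HOIP:0060455"
#> [5] "HOIP:0060504" "HOIP:0060512"

## the mechanistic chain behind the first of those causes
causalPaths(graph, "HOIP:0060431", "HOIP:0060427", 6)[[1]]
#> [1] "HOIP:0060431" "HOIP:0060453" "HOIP:0060455" "HOIP:0060432" "HOIP:0060427"

## four-stage homeostatic-imbalance pattern of the chronic course
checkCoursePattern(graph, "HOIP:0060195")
#> PatternReport for HOIP:0060195
#>   stages present: stress_demand, stress_response, imbalance, outcome
#>   missing: (none)
#>   witness: HOIP:0060431 -> HOIP:0060321 -> HOIP:0099013 -> HOIP:0060240
```

The first query says: within the chronic course associated with type 2
diabetes, telomere shortening (HOIP:0060431), pancreatic beta-cell
exhaustion (HOIP:0060453), positive regulation of SASP secretion
(HOIP:0060455), SASP secretion (HOIP:0060432), FOXO signaling
(HOIP:0060504) and TLR4 signaling (HOIP:0060512) are the entailed upstream
causes of insulin resistance — the first four via one transitive chain,
which the path query spells out.  The pattern report shows the chronic
course instantiating the full imbalance model, from the telomere-shortening
stressor through the p53 stress response and the homeostatic imbalance to
sustained cellular senescence.

A command-line wrapper ships with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "hoipr-cli.R", package = "hoipr"))')" \
    gen-fixture --out senescence.ttl
```

with subcommands `convert`, `materialize`, `causes`, `results`, `paths`,
`cross-course`, `check-pattern`, `export-viz` and `gen-fixture`.

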