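---
title: "Modelling cellular senescence as homeostasis-imbalance process courses"
author: "hoipr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cellular senescence as homeostasis-imbalance process courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hoipr)
```

## The model

`hoipr` works with a deliberately small OWL-DL fragment.  A document holds
three kinds of facts:

* **Terms** — named classes with an entity kind (course, process,
  material entity, role, disease, symptom, phenotype, anatomical entity)
  and annotations (label, textual definition, description, database
  cross-references, taxon, a negation marker, a homeostatic-imbalance
  stage tag, and an equivalence note for duplicate identifiers).
* **Relations** — object properties with logical characteristics:
  transitivity, an inverse partner, or a two-element property chain, plus
  optional domain/range entity kinds.
* **Axioms** — either named-class subsumptions `A ⊑ B` or existential
  restrictions `A ⊑ ∃R.B` over a *named* filler.

The modelling assumption throughout is class-level causality: an
existential restriction on the causal relation is read as a directed edge
between process classes.  There are no individuals, no universal
restrictions, no intersections and no complement classes; "no X" processes
(such as *no SASP secretion* downstream of senolytic intervention) are
ordinary process terms carrying a boolean negation marker, because a
logical complement is both outside the fragment and not how such nodes are
used — they are rendered as plain grey nodes in visualizations.

A *course* is a process sequence: its member processes are attached with
`has_part`.  Courses form a subclass hierarchy (embryonic and adult under
the root senescence course; acute and chronic under adult; the
diabetes-associated and senolytics courses under chronic), and membership
is inherited along it.

## The relation registry

`canonicalRelationRegistry()` fixes eight relations.  Only the causal pair
`has_result`/`has_cause` is transitive — that single axiom is what turns a
curated set of direct links into a queryable causal network.
`has_part_result` is defined by the chain `has_part ∘ has_result`, so a
whole process (DDR signaling) is connected to what its parts (ATM/ATR
signaling) bring about (p21 signaling).  `realizes_disease` is constrained
to processes as domain and diseases as range, `manifests_symptom` to
symptom objects and `has_role` to role objects; `validateDocument()`
checks every existential axiom against these constraints and reports
violations and dangling references as data rather than failing.

Whether `has_part` should itself be transitive is not settled in the
modelling tradition this package follows; the default is *not transitive*
(only the causal pair is), switchable via
`canonicalRelationRegistry(partTransitive = TRUE)`.

## Reasoner semantics

`materialize()` computes the closure under six rules: subsumption
transitivity (R1), restriction inheritance down the subject hierarchy
(R2), filler generalization up the object hierarchy (R3), transitivity of
the causal pair (R4), property chains (R5) and inverse completion (R6).

One design decision deserves spelling out.  If R6 participated in the same
fixpoint as R2/R3, the three rules would compose through the inverse
relation: an edge could travel *up* the subject hierarchy (invert,
generalize the filler, invert back) as well as down, and by zig-zagging
through shared superclasses any two classes in the same undirected
subsumption component would end up sharing all their causal edges —
including inferred self-causes on perfectly acyclic graphs, and causal
links between unrelated sibling pathways that merely share an
innate-immunity ancestor.  No DL reasoner licenses those inferences, and
they would drown the curated network in noise.  `hoipr` therefore runs
R2–R5 on a canonical orientation per inverse pair (`has_result` for the
causal pair, `has_part` for the part-whole pair; axioms asserted in the
inverse orientation are flipped at intake) and applies R6 once, as a
completing pass.  The duality the inverse pair exists for — `X` is a cause
of `Y` exactly when `Y` is a result of `X` — holds by construction, while
restrictions propagate only subject-down and filler-up, as in a sound
reasoner.

Evaluation is semi-naive (only newly derived edges re-fire rules) with a
sorted frontier, so derivation traces are reproducible; each derived edge
stores the first derivation found under that deterministic order, not all
proofs.  Reflexive subsumption stays implicit.  Cycles are permitted —
biological feedback is real — and termination is guaranteed because rules
only add edges over a finite universe; on a causal cycle every ordered
pair (including self-pairs) is entailed, which is the honest reading of a
feedback loop under transitivity.

Two independent implementations guard the engine: `bruteForceClosure()`
re-applies every rule to every fact with naive data-frame joins until
fixpoint (guarded to ≤ 200 classes), and `randomOntology()` computes its
ground truth by boolean matrix algebra — lift the asserted adjacency with
reflexive-transitive subsumption sandwiches, Warshall-close the transitive
relations, multiply for the chain.  The test suite requires exact edge-set
agreement of all three on seeded random ontologies.

## Course queries

* **Membership and specialization.** `courseMembers()` takes the direct
  `has_part` fillers and adds the parts inherited from every supercourse.
  The detection rule for specialization — the one genuinely open design
  point — is subsumption-based: an asserted part of a subcourse *replaces*
  an inherited part exactly when it is a proper subclass of it in the
  materialized hierarchy (sustained cellular senescence replacing cellular
  senescence in the chronic course); otherwise it is an added part.
* **Scoping.** `causesOf()`/`resultsOf()` are computed on the whole
  closure and then filtered to course members, and querying a process
  outside the named course is an error.  Cross-course leakage is opt-in:
  `crossCourseResults()` deliberately looks through the course-specific
  subclasses of a process (the per-course IL-8 signaling variants) and
  reports, per course, what they entail within that course.
* **Paths.** `causalPaths()` enumerates simple paths over *asserted*
  causal edges only — the inferred transitive edges would collapse every
  path to length one — while entailment queries always use the closure.
  `maxLen` counts edges; `src == dst` returns the trivial path by
  convention.  Simple-path enumeration is delegated to igraph.
* **Generalization.** `commonGeneralizedProcesses()` reports, for member
  pairs of two courses, their least common superclass, with ties broken by
  identifier order.  Which ancestors are "trivial" is not derivable from
  the data, so hub classes are excluded via an argument defaulting to the
  document's `roots` metadata (the curated ontology lists its two
  top-level hubs).  `generalizedCausalNetwork()` merges courses under a
  user-chosen abstraction map, validated against the hierarchy.

Everywhere, output order is lexicographic by normalized CURIE, so results
are deterministic.

## The four-stage imbalance pattern

The unified representation of a senescence course has four stages: stress
(functional demand), stress response (functioning process), homeostatic
imbalance, and outcome.  Stage tags are *curator-supplied annotations*,
not inferred classifications — the pattern is a representation template,
and no label heuristic can decide that p53 signaling is "the response" in
one course and part of the outcome chain in another.  A convenience
pre-tagger (`preTagStages()`) exists but never overwrites a curated tag.
`checkCoursePattern()` then searches for an ordered witness, one member
per stage, requiring *causal entailment* (not direct edges) between
consecutive stages, matching the coarse arrows of the model; the
lexicographically first witness is reported.  Whether a demand process is
formally paired with "its" response is left to curation — the model names
no such property.

## Serialization

Turtle and RDF/XML readers and writers cover exactly the fragment: class
declarations with annotations, property declarations
(`owl:TransitiveProperty`, `owl:inverseOf`, `owl:propertyChainAxiom`),
named subsumptions and subclass-of-restriction axioms with
`owl:someValuesFrom` over a named filler.  Everything else — universal
restrictions, anonymous nested fillers, equivalence/intersection
constructs — is skipped and itemized in a `ParseReport`.  Blank nodes are
skolemized in document order, so two parses of the same bytes give
identical documents *and identical reports*.  The annotation IRIs for
definition, description and cross-reference are not standardized across
ontology releases, so they are configurable (`annotationConfig()`) with
OBO-convention defaults (IAO definition, Dublin Core description,
oboInOwl `hasDbXref`).  Stage tags, negation markers, entity kinds, taxa
and equivalence notes are persisted as vocabulary annotations and survive
round-trips; axiom provenance is the one field that does not.

## The curated ontology and what it does (not) show

`senescenceOntology()` encodes the demonstration knowledge model: the
course taxonomy with its published textual definitions, the per-course p21
chains (ATM → p53 → regulation of gene expression by p53 → p21 in the
adult course; TGF-beta → SMAD → regulation by SMAD → p21 in the embryonic
course), DDR signaling with ATM/ATR parts, SASP secretion with its IL-6/
IL-8 subprocesses, outputs, role and location, the telomere-shortening →
beta-cell-exhaustion → SASP → insulin-resistance chain with FOXO and TLR4
as parallel causes, the LMNB1 → cytosolic chromatin fragments →
cGAS → STING → IRF chain, the senolytics branch (metformin negatively
regulating NFKB, with negation-marked downstream nodes), two COVID-19
courses carrying course-specific IL-8 variants for cross-course inference,
and stage tags for the embryonic, acute and chronic courses.

Details worth knowing:

* Published identifiers are used wherever they exist.  The knowledge model
  prints *duplicate* identifiers for a few classes (two p53-signaling ids,
  two IL-6-signaling ids, and an eight-digit variant spelling of the
  embryonic course id); these are kept as distinct terms cross-linked with
  an `equivalent_to` annotation, with the seven-digit form treated as
  canonical for the embryonic course.
* Entities named only in prose carry synthetic identifiers in the
  `HOIP:0099***` range (clearly segregated from published ones), including
  the per-course homeostatic-imbalance nodes and the COVID course classes.
* Course-specific signaling variants are subclasses of their generic
  class (IL-8 variants under CXCL8 signaling; the diabetes-context SASP
  secretion under SASP secretion), which is what drives cross-course
  queries.
* Metformin's involvement is recorded as an annotation on the
  negative-regulation process (description plus a CHEBI cross-reference)
  rather than a directed edge, since the direction of a
  participation-style property is not part of the fragment.
* The "very high"/"severe" qualifiers on COVID process labels are plain
  label text with no formal semantics.

The fixture emulates the *structure* of the real ontology — course
composition, specialization, chains, cross-course variants, attachments —
at about 80 classes.  It does not emulate the scale of a full release
(hundreds of terms across ten-plus imported ontologies), its annotation
density, or curation noise (spelling variants, dangling imports beyond the
ones deliberately included).  Green tests therefore certify the machinery
and the encoded causal structure, not the completeness of any real
knowledge base; `readOntology()` is the intended path for real releases,
with the parse report making explicit what falls outside the fragment.

`randomOntology()` generates the adversarial counterpart: seeded subclass
forests, causal DAGs with optional injected cycles and a fraction of edges
asserted in the inverse orientation, and part-whole edges whose density
(`chainDensity`) controls how many chain entailments arise.  Defaults
(30 classes, out-degree ≤ 3, chain density 0.3, specialization rate 0.2)
keep closures in the hundreds of edges — large enough to exercise every
rule interaction, small enough that the brute-force oracle stays fast.

## Problem sizes and numerical choices

The test suite cross-checks the three closure implementations on 125
random ontologies of 10–50 classes (25 in the unit tests, 100 in the
end-to-end suite), round-trips 21 documents through both serializations,
and runs every course query against the curated ontology; the full suite
completes in under two minutes on one CPU.  There are no tolerances
anywhere — every comparison in this package is exact (set equality of
edges, byte equality of exports), which is the appropriate standard for
symbolic computation.  Degenerate inputs are handled explicitly: empty
documents materialize to empty graphs, empty courses have empty
membership, empty graphs export to valid empty documents, and generator
parameters outside their ranges raise errors rather than silently
clamping.

## Limitations

* No consistency checking: the fragment cannot express contradiction, so
  there is nothing to detect; disjointness and unsatisfiability are out of
  scope.
* No quantitative causality: edges are qualitative, and no numeric
  "degree of imbalance" is attempted — the four-stage pattern is checked
  structurally.
* Derivations record one proof, not all proofs.
* The OBO-format and SPARQL-endpoint ecosystems are out of scope; queries
  are answered natively against the materialized closure.
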