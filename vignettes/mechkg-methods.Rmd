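---
title: "Methods: rule-based DDI mechanism inference over a mechanistic knowledge graph"
author: "mechkg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based DDI mechanism inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Most computational DDI methods output an association score for a drug
pair. This package takes the complementary, mechanism-centered route:
it encodes what is known about two drugs — their actions on
metabolizing enzymes and transporters, and their pharmacological,
biomolecular, physiological and genetic features — as a knowledge
graph, and treats "drugs A and B may interact" as a *hypothesis to be
proven*. A backward-chaining Horn-rule engine either proves the
hypothesis, returning the full proof tree (the explanation), or
rejects it. Absence of evidence is always a rejection, never a derived
fact: the engine has no negation, which matches the accept/reject
semantics of hypothesis checking and keeps the logic monotone.

The pipeline is ETL → validation → inference:

1. **ETL.** Pipe-delimited terminology files (`MRCONSO`:
   `CUI|SAB|CODE|STR`, `MRREL`: `CUI1|REL|RELA|CUI2|SAB`, `MRSAT`:
   `CUI|ATN|ATV`) provide concepts, relationships and attributes keyed
   by CUI-style identifiers; CSV link tables in the style of DrugBank
   and PharmGKB records are joined by shared identifiers. A record
   that carries both an external id and a CUI registers an alias, so
   later records with the external id alone still land under the CUI;
   records with no resolvable CUI are kept under a source-prefixed id
   (`DB:…`, `PGKB:…`) and listed in the load report — reported, never
   silently dropped.
2. **Validation.** Instances are classified into a four-class /
   seven-subclass ontology via their semantic-type codes, then the
   graph is checked structurally: class conflicts, unknown predicates
   and domain/range violations are violations; unclassified entities
   are warnings by default, because real terminology loads always
   contain types outside any curated map.
3. **Inference.** Six rules in two layers (four
   pharmacological-effect rules, one shared-feature rule, one
   combination rule), evaluated by tabled backward chaining.

## Assumptions worth stating

* **Semantic types live in the attribute file.** This package reads
  semantic-type codes from `MRSAT`-dialect rows with `ATN = SEMTYPE`.
  Released UMLS distributions keep semantic types in a separate
  `MRSTY` table; the dialect here deliberately models them as
  attributes, which keeps the source-file contract at three files and
  one attribute convention. Nothing prevents exporting `MRSTY` content
  into this dialect.
* **Transporters are proteins.** The ontology's printed seven
  subclasses contain `enzymes` but no transporter subclass.
  Transporters (e.g. ABCB1) are placed in `enzymes` and distinguished
  by a functional annotation predicate, `has_role(t,
  metabolizing_enzyme | transporter)`. This preserves the seven-subclass
  schema while letting the rule layer separate enzyme from transporter
  mechanisms.
* **The drug–protein action qualifiers are asserted facts.** Whether a
  drug inhibits, induces or is a substrate of a protein arrives in the
  link CSV as an explicit relation; the package does not infer
  qualifiers from other evidence.

## The rule base, and the choices inside it

The rule file (`inst/rules/ddi_rules.yaml`) is configuration, not
code, and can be revised without touching the engine. Decisions made
in its reconstruction:

* **Six rules, fixed.** Four layer-1 rules (inhibition/induction ×
  enzyme/transporter), one layer-2 shared-feature rule, one
  combination rule. The feature-to-level mapping needed by the
  layer-2 rule is *not* expressed as extra rules — it lives in the
  predicate registry as a virtual ternary view `feature(drug, level,
  value)` — precisely so the rule count stays at six.
* **`neq` guards in layer 1.** A drug can inhibit an enzyme it is
  also a substrate of; without the guard it would become its own
  perpetrator. The perpetrator ≠ victim constraint is part of what a
  mechanism match *means*, so the guard sits in the rules.
* **"Either direction" via a pair builtin.** The combination rule
  must fire for a pair regardless of which drug perpetrates, but Horn
  bodies have no disjunction and splitting into two rules would break
  the six-rule cardinality. The engine therefore provides a small
  generative builtin `pair(?x, ?y, ?a, ?b)` that enumerates both
  orderings of a ground pair; `potential_ddi` consequently holds in
  both orderings, making assessments symmetric by construction.
* **Aggregates are monotone.** The combination rule's condition
  "number of distinct shared levels ≥ θ" is the aggregate builtin
  `countd(…) >= θ`. Only `>=` and `>` comparisons are accepted, and a
  rule base whose aggregate inner predicate depends on the
  aggregating rule's own head is rejected at load time. Monotone,
  stratified aggregates keep the least fixpoint well-defined, so the
  backward chainer and the forward closure provably agree.
* **θ defaults to 1.** The framework requires feature sharing
  alongside a mechanism but no particular cutoff; any shared level
  suffices by default. "Sharing the *maximum* number of features" is
  honored separately by `rankPairs()`, which orders candidate pairs
  by shared-level count, then feature-match count, then
  mechanism-match count, with lexicographic tie-breaks — both
  readings (per-pair threshold, across-pairs ranking) are available
  without hard-wiring either.
* **Six similarity levels.** The four ontology levels plus
  `substructure` and `contraindication`. The case study's similarity
  evidence — mutual contraindication on hypersensitivity, a shared
  physiological effect, and shared substructure classes — spans
  exactly three of these levels; folding substructures or
  contraindications into the four core levels would double-count
  evidence and make that "three levels" irreproducible. Substructure
  sharing is asserted-literal matching on controlled class names, not
  computed chemical fingerprinting: the sources provide named classes,
  not structures.

## The inference engines

`backwardChain()` evaluates only the rules in the goal predicate's
dependency cone, memoizes answers in per-predicate tables, and runs to
a local fixpoint — tabling makes recursive terminology rules (e.g. an
`ancestor_of` closure over `parent_of`) terminate even on cyclic
graphs. Proof extraction then walks the saturated tables top-down: one
proof per distinct rule instantiation, children taking their first
proof, with a path guard that blocks cyclic derivations so proofs are
minimal and extraction terminates. `forwardClosure()` is a separately
written bottom-up engine (row-at-a-time textbook unification, no code
shared with the query path) that computes the least model; the test
suite requires exact agreement between the two on fuzzed graphs, which
is the package's central correctness property.

Derived facts of arity above two (`mech/4`, `shared/4`) are stored in
closure output as triples whose object carries the trailing arguments
joined by `;` (escaped inside values), so a closed graph can be
serialized, reloaded and re-closed without change (idempotence is
tested).

## Determinism and numerical choices

There is no floating-point numerics in the method; the numerical
discipline here is *ordering*. Every user-visible sequence — match
results, proof lists, serialized triples, report rows — is sorted
lexicographically under C collation (`method = "radix"`), so output is
byte-identical across runs, platforms and locales. RDF exports carry
per-triple provenance in the predicate IRI namespace
(`…/rel/<PROVENANCE>/<predicate>`) and entity annotations as `meta/`
triples, making `deserialize(serialize(g))` lossless in all three
formats without RDF reification. Ties in `rankPairs()` break on the
lexicographic pair id, giving a total order.

## The synthetic-data generator

`simulateSources()` emulates the *shape* of the real integration
problem at desk scale: a small pharmacopeia of drugs acting on a
handful of role-annotated enzymes and transporters, sparse background
action and feature facts, and a few planted DDI pairs guaranteed to
satisfy the rule framework at θ = 1. Defaults (12 drugs, 4 enzymes, 2
transporters, 3 candidate values per feature level, action
probabilities 0.04–0.15, feature probability 0.12, 2 planted pairs)
are chosen so that most pairs share nothing — mirroring the sparsity
of real pharmacology — while chance-formed mechanisms still occur.
Because they do occur, the recorded ground truth is *not* the planted
list but the full rule-satisfying set, enumerated exhaustively (and
independently of either inference engine) at generation time;
otherwise chance DDIs would read as false positives. Output is
byte-identical under a fixed seed.

What the generator does **not** emulate — and what passing tests on it
therefore cannot show: terminology scale (millions of concepts),
label noise and synonymy, inconsistent or contradictory source
assertions, dose- or exposure-dependence of interactions, and any
quantitative pharmacokinetics. The generator exercises the pipeline's
logic, not the epistemics of real curation.

Problem sizes used by the test suite were chosen to keep the full run
in the low minutes while still giving the property tests real
coverage: 1,000 fuzzed graphs (≤ ~60 triples) for engine agreement, 20
simulation seeds for all-pairs planted-truth recovery, 100 seeds for
planted-defect consistency detection.

## Degenerate inputs and edge behavior

Empty files parse to empty record sets; an entirely malformed file is
treated as the wrong dialect and refused. A drug assessed against
itself is a precondition error (the rules would reject it anyway via
`neq`, but silently returning NO_EVIDENCE would mask a caller bug).
Unknown drug identifiers are hard errors naming the offending id.
Patterns with no variables act as membership tests. An empty graph is
consistent and proves nothing.

## Known limitations

* The consistency check is structural (class membership, predicate
  vocabulary, domain/range); it is not a description-logic reasoner
  and will not find, e.g., unsatisfiable class intersections.
* Rule bodies cannot use negation; phenomena like "interacts unless
  co-administered with an inducer" are out of scope.
* The RDF writers/parsers cover the subset of N-Triples/Turtle this
  package emits (plus simple standard files); they are not a general
  RDF toolkit.
* Evidence is unweighted: every shared feature level counts equally,
  and the verdict is binary. Ranking is ordinal, not probabilistic.
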