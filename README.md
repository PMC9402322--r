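# mechkg: mechanistic knowledge graphs and rule-based DDI inference

`mechkg` is an R package for exploring and *explaining* the biological
mechanisms behind potential drug–drug interactions (DDIs). Rather than
scoring drug pairs with a black-box model, it builds a mechanistic
knowledge graph from heterogeneous biomedical sources, validates the
graph against a small pharmacological ontology, and then *proves or
rejects* the hypothesis "these two drugs may interact" with a
backward-chaining Horn-rule engine. An accepted hypothesis comes with a
proof tree: which drug is the perpetrator (inhibitor or inducer), which
is the victim (substrate), on which metabolizing enzyme or transporter,
and which biomedical features the two drugs share.

It is aimed at researchers in pharmacovigilance, drug safety and
clinical pharmacology who want interpretable, evidence-backed DDI
hypotheses from terminology-scale data — and at anyone who needs a
compact, fully testable Horn-rule reasoner over RDF-style triples in R.

## The model

Facts are triples over CUI-style concept identifiers, assembled from
pipe-delimited terminology files (`MRCONSO`/`MRREL`/`MRSAT` dialects)
and CSV link tables in the style of DrugBank and PharmGKB records,
joined on shared identifiers. Instances are classified into a
four-class ontology (pharmacological, biomolecular, physiological,
genetic; seven subclasses) through their semantic-type codes, and the
graph is checked for structural consistency before any inference.

Inference is a two-layer rule base of six Horn rules. Writing
`inh(a,t)`, `ind(a,t)`, `sub(b,t)` for the asserted
inhibits/induces/substrate-of relations and `role(t,·)` for the
enzyme/transporter annotation:

* **Layer 1 — pharmacological effects** (R1–R4):
  `inh(a,t) ∧ sub(b,t) ∧ role(t,k) ∧ a≠b → mech(a,b,t,inhibition)`
  and the analogous rule with `ind` for induction, each for
  `k ∈ {metabolizing_enzyme, transporter}`.
* **Layer 2 — shared biomedical features** (R5):
  `feature(a,l,v) ∧ feature(b,l,v) ∧ a≠b → shared(a,b,l,v)`, where
  `feature` is the registry-driven view of the graph's feature
  predicates and `l` ranges over the four ontology levels plus
  substructure classes and contraindications.
* **Combination** (R6): a pair is a `potential_ddi` when some
  layer-1 mechanism links it (in either direction) and the number of
  distinct shared levels reaches the threshold θ (default 1).

Goals are answered by a tabled, goal-directed backward chainer;
an independently coded bottom-up forward-closure engine serves as the
soundness/completeness oracle in the test suite. Everything is
deterministic: identical inputs give byte-identical graphs, proofs and
reports.

## Worked example

The package ships a generator for a canonical desk-scale fixture: the
irinotecan (a topoisomerase-inhibitor chemotherapy agent) +
levofloxacin (a fluoroquinolone antibiotic) case, written in the same
file dialects the ETL reads.

```r
library(mechkg)

fixture <- canonicalFixture(tempfile())
built <- buildGraphFromFiles(fixture$files[["mrconso"]],
                             fixture$files[["mrrel"]],
                             fixture$files[["mrsat"]],
                             fixture$files[["links"]])
graph <- classifyGraph(built$graph, defaultSchema())
graph
#> KnowledgeGraph: 43 triples over 10 entities
#>   provenance: DRUGLINK=34, GENELINK=2, MRREL=7

checkConsistency(graph, defaultSchema())
#> ConsistencyReport: consistent (0 violations, 0 warnings)

ddi <- assessDDI(graph, "C9000001", "C9000002", theta = 1)
ddi
#> DDIAssessment: C9000001 vs C9000002 -> POTENTIAL_DDI
#>   mechanism matches: 2; shared feature levels: 3 (theta = 1)
```

The two mechanism matches say that levofloxacin acts as an inhibitor
of both CYP3A4 (a metabolizing enzyme) and ABCB1 (an efflux
transporter) while irinotecan is a substrate of both — the classic
perpetrator/victim pattern in which inhibition raises the victim's
exposure. The three shared feature levels are the contraindication
profile (hypersensitivity to either agent), a physiological effect
(decreased DNA integrity) and 14 shared substructure classes.
`renderReport(ddi, "markdown", graph = graph)` renders the summary
table; the enzyme row reads:

```
| Metabolizing enzymes | CYP3A4 substrate | CYP3A4 inhibitor |
| Transporters         | ABCB1 substrate  | ABCB1 inhibitor  |
```

and `renderReport(ddi, "json")` emits the machine-readable report
(validated by `validateReportJSON()`), including the proof trees.

A command-line front end wraps the same pipeline:

```sh
mechkg build --mrconso mrconso.rrf --mrrel mrrel.rrf --mrsat mrsat.rrf \
             --links links.csv --out graph.ttl --report load.json
mechkg validate graph.ttl
mechkg infer graph.ttl --drug-a C9000001 --drug-b C9000002 --format markdown
mechkg simulate --out simdir --seed 11
```

(the script is installed at `system.file("scripts", "mechkg",
package = "mechkg")`).

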