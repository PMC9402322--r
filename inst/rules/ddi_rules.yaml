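# The six-rule, two-layer DDI framework.
#
# Layer 1 (pharmacological effects): a perpetrator drug ?a inhibits or
# induces a metabolizing enzyme or transporter ?t of which the victim
# drug ?b is a substrate.
# Layer 2 (shared biomedical features): the two drugs share a feature
# value ?v at similarity level ?l; feature/3 is the virtual view over
# the registered feature predicates.
# Combination: a potential DDI holds for a pair, in both orderings,
# when some layer-1 mechanism links the pair in either direction and
# the number of distinct shared feature levels reaches the threshold.
- id: R1
  layer: 1
  head: "mech(?a, ?b, ?t, inhibition)"
  body:
    - "inhibits(?a, ?t)"
    - "substrate_of(?b, ?t)"
    - "has_role(?t, metabolizing_enzyme)"
    - "neq(?a, ?b)"
- id: R2
  layer: 1
  head: "mech(?a, ?b, ?t, induction)"
  body:
    - "induces(?a, ?t)"
    - "substrate_of(?b, ?t)"
    - "has_role(?t, metabolizing_enzyme)"
    - "neq(?a, ?b)"
- id: R3
  layer: 1
  head: "mech(?a, ?b, ?t, inhibition)"
  body:
    - "inhibits(?a, ?t)"
    - "substrate_of(?b, ?t)"
    - "has_role(?t, transporter)"
    - "neq(?a, ?b)"
- id: R4
  layer: 1
  head: "mech(?a, ?b, ?t, induction)"
  body:
    - "induces(?a, ?t)"
    - "substrate_of(?b, ?t)"
    - "has_role(?t, transporter)"
    - "neq(?a, ?b)"
- id: R5
  layer: 2
  head: "shared(?a, ?b, ?l, ?v)"
  body:
    - "feature(?a, ?l, ?v)"
    - "feature(?b, ?l, ?v)"
    - "neq(?a, ?b)"
- id: R6
  layer: 3
  head: "potential_ddi(?a, ?b)"
  body:
    - "mech(?x, ?y, ?t, ?r)"
    - "pair(?x, ?y, ?a, ?b)"
    - "countd(?l, shared(?a, ?b, ?l, ?v)) >= {theta}"
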