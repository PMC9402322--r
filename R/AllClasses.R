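#' @import methods
NULL

#' KnowledgeGraph: a set of subject-predicate-object triples over
#' concept-identified entities
#'
#' The central container of the package. Triples are kept with set
#' semantics (re-adding an existing triple is a no-op) in a data frame
#' with columns `subject`, `predicate`, `object`, `literal` (logical:
#' is the object a literal string rather than a concept id) and
#' `provenance` (one of `MRCONSO`, `MRREL`, `MRSAT`, `DRUGLINK`,
#' `GENELINK`, `FIXTURE`, `INFERRED`). Every concept id appearing in a
#' triple has an entity record carrying labels, semantic-type codes
#' and (after classification) ontology class assignments.
#'
#' @slot triples data.frame of triples, see above.
#' @slot entities named list; each element holds `labels`
#'   (character), `semtypes` (character, UMLS-style type codes),
#'   `coreClass`, `subclass` (character NA until classified) and
#'   `subclassCandidates` (character, non-empty when the semantic
#'   types map to several subclasses).
#'
#' @seealso [emptyGraph()], [addTriple()], [matchTriples()]
#' @export
setClass("KnowledgeGraph",
  representation(triples = "data.frame", entities = "list"),
  prototype(triples = emptyTripleFrame(), entities = list()))

setValidity("KnowledgeGraph", function(object) {
  tr <- object@triples
  need <- c("subject", "predicate", "object", "literal", "provenance")
  if (!all(need %in% names(tr)))
    return(sprintf("triples must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(tripleKey(tr)))
    return("duplicate triples present (set semantics violated)")
  ids <- unique(c(tr$subject, tr$object[!tr$literal]))
  missing <- setdiff(ids, names(object@entities))
  if (length(missing) > 0L)
    return(sprintf("entity record missing for '%s'", missing[[1L]]))
  TRUE
})

#' Schema: the four-class / seven-subclass DDI ontology
#'
#' Core classes cover the pharmacological, biomolecular, physiological
#' and genetic levels; the seven subclasses (drugs; genes, enzymes,
#' biological processes; effect, mechanism of action; SNPs) each map
#' to exactly one core class. Instances are assigned to subclasses
#' through their semantic-type codes via `semtypeMap`, and relation
#' domain/range constraints are recorded per predicate.
#'
#' @slot coreClasses character(4).
#' @slot subclasses named character: subclass -> core class.
#' @slot semtypeMap named character: semantic-type code -> subclass.
#' @slot relationConstraints named list: predicate -> list(subject =
#'   allowed subject subclasses, object = allowed object subclasses or
#'   the keyword "literal", values = optional controlled literal set).
#' @seealso [defaultSchema()], [classifyGraph()], [checkConsistency()]
#' @export
setClass("Schema",
  representation(coreClasses = "character", subclasses = "character",
                 semtypeMap = "character", relationConstraints = "list"))

setValidity("Schema", function(object) {
  if (length(object@coreClasses) != 4L) return("exactly 4 core classes required")
  if (length(object@subclasses) != 7L) return("exactly 7 subclasses required")
  if (is.null(names(object@subclasses)) || anyDuplicated(names(object@subclasses)))
    return("subclasses must be uniquely named")
  if (!all(object@subclasses %in% object@coreClasses))
    return("every subclass must map to a declared core class")
  if (!all(object@semtypeMap %in% names(object@subclasses)))
    return("semtypeMap values must be declared subclasses")
  TRUE
})

#' ConsistencyReport: result of the structural ontology check
#'
#' @slot violations data.frame with columns `kind` (one of
#'   `UNCLASSIFIED`, `MULTI_CLASS_CONFLICT`, `DOMAIN_VIOLATION`,
#'   `RANGE_VIOLATION`, `UNKNOWN_PREDICATE`), `item` (entity id or
#'   triple rendering) and `detail`.
#' @slot warnings data.frame, same columns; warn-level findings
#'   (unclassified entities under default strictness).
#' @slot isConsistent logical; `TRUE` iff `violations` is empty.
#' @export
setClass("ConsistencyReport",
  representation(violations = "data.frame", warnings = "data.frame",
                 isConsistent = "logical"))

setValidity("ConsistencyReport", function(object) {
  if (!identical(object@isConsistent, nrow(object@violations) == 0L))
    return("isConsistent must hold exactly when violations is empty")
  TRUE
})

#' LoadReport: per-source accounting for a graph build
#'
#' @slot perSource data.frame with columns `source`, `parsed`,
#'   `skipped`, `triples`.
#' @slot unresolvedLinks character: external ids that could not be
#'   resolved to a CUI (they are still loaded under a prefixed id).
#' @export
setClass("LoadReport",
  representation(perSource = "data.frame", unresolvedLinks = "character"))

#' Rule: a range-restricted Horn rule over triple patterns
#'
#' The head is a single atom; the body is an ordered conjunction of
#' relation atoms and builtins (`neq`, the pair-orientation generator
#' `pair`, and the monotone aggregate `countd`). Every head variable
#' must be bound by the body (range restriction), checked at load.
#'
#' @slot id character rule identifier.
#' @slot layer integer: 1 = pharmacological-effect layer, 2 =
#'   shared-feature layer, 3 = combination.
#' @slot head list atom.
#' @slot body list of atoms.
#' @export
setClass("Rule",
  representation(id = "character", layer = "integer",
                 head = "list", body = "list"))

#' RuleBase: an ordered collection of rules plus the shared-feature
#' threshold
#'
#' @slot rules list of [Rule-class] objects.
#' @slot theta numeric: minimum number of distinct shared biomedical
#'   feature levels required by the combination rule.
#' @seealso [defaultRuleBase()], [readRuleBase()]
#' @export
setClass("RuleBase",
  representation(rules = "list", theta = "numeric"))

#' ProofResult: verdict and proof trees for a queried goal
#'
#' `status` is `ACCEPTED` exactly when at least one proof exists.
#' Proof trees are nested lists: rule-application nodes carry
#' `type = "rule"`, `rule`, `layer`, `bindings` and `children`; leaf
#' nodes carry `type = "fact"` with the supporting triple and its
#' provenance; builtin nodes carry `type = "builtin"`.
#'
#' @slot goal list: the queried atom.
#' @slot status character: `ACCEPTED` or `REJECTED`.
#' @slot bindings data.frame: one row per distinct answer substitution
#'   (zero columns for a ground goal).
#' @slot proofs list of proof trees, deterministically ordered.
#' @export
setClass("ProofResult",
  representation(goal = "list", status = "character",
                 bindings = "data.frame", proofs = "list"))

setValidity("ProofResult", function(object) {
  if (!object@status %in% c("ACCEPTED", "REJECTED"))
    return("status must be ACCEPTED or REJECTED")
  if (!identical(object@status == "ACCEPTED", length(object@proofs) > 0L))
    return("ACCEPTED exactly when proofs is non-empty")
  TRUE
})

#' MechanismMatch: one pharmacological-effect (layer 1) finding
#'
#' A perpetrator drug inhibits or induces a metabolizing enzyme or
#' transporter of which the victim drug is a substrate.
#'
#' @slot target concept id of the enzyme/transporter.
#' @slot targetKind `"metabolizing_enzyme"` or `"transporter"`.
#' @slot perpetrator,victim drug concept ids (never equal).
#' @slot perpetratorRole `"inhibitor"` or `"inducer"`.
#' @slot ruleId the layer-1 rule that fired.
#' @slot proof proof tree (list).
#' @export
setClass("MechanismMatch",
  representation(target = "character", targetKind = "character",
                 perpetrator = "character", perpetratorRole = "character",
                 victim = "character", ruleId = "character", proof = "list"))

setValidity("MechanismMatch", function(object) {
  if (identical(object@perpetrator, object@victim))
    return("perpetrator and victim must differ")
  if (!object@targetKind %in% c("metabolizing_enzyme", "transporter"))
    return("targetKind must be metabolizing_enzyme or transporter")
  if (!object@perpetratorRole %in% c("inhibitor", "inducer"))
    return("perpetratorRole must be inhibitor or inducer")
  TRUE
})

#' FeatureMatch: one shared biomedical feature (layer 2) finding
#'
#' @slot level similarity level: one of `pharmacological`,
#'   `biomolecular`, `physiological`, `genetic`, `substructure`,
#'   `contraindication`.
#' @slot value the shared concept id or literal.
#' @slot evidence list of the two supporting leaf triples.
#' @export
setClass("FeatureMatch",
  representation(level = "character", value = "character",
                 evidence = "list"))

#' DDIAssessment: the two-layer verdict for a drug pair
#'
#' Verdict is `POTENTIAL_DDI` exactly when at least one mechanism
#' match exists and the number of distinct shared feature levels
#' reaches the threshold; otherwise `NO_EVIDENCE`.
#'
#' @slot drugA,drugB drug concept ids.
#' @slot threshold numeric shared-level threshold used.
#' @slot mechanismMatches list of [MechanismMatch-class].
#' @slot featureMatches list of [FeatureMatch-class].
#' @slot sharedLevelCount integer: distinct levels with >= 1 match.
#' @slot verdict `POTENTIAL_DDI` or `NO_EVIDENCE`.
#' @slot rationale character vector of explanation lines.
#' @slot proof list: proof trees of the accepted combination goal
#'   (empty when verdict is `NO_EVIDENCE`).
#' @seealso [assessDDI()], [renderReport()]
#' @export
setClass("DDIAssessment",
  representation(drugA = "character", drugB = "character",
                 threshold = "numeric", mechanismMatches = "list",
                 featureMatches = "list", sharedLevelCount = "integer",
                 verdict = "character", rationale = "character",
                 proof = "list"))

setValidity("DDIAssessment", function(object) {
  lv <- unique(vapply(object@featureMatches, function(m) m@level, ""))
  if (!identical(object@sharedLevelCount, length(lv)))
    return("sharedLevelCount must equal distinct levels over featureMatches")
  want <- if (length(object@mechanismMatches) > 0L &&
              object@sharedLevelCount >= object@threshold)
    "POTENTIAL_DDI" else "NO_EVIDENCE"
  if (!identical(object@verdict, want))
    return("verdict inconsistent with mechanism/shared-level invariant")
  TRUE
})

#' FeatureProfile: every graph fact touching one drug, grouped two ways
#'
#' @slot drug the profiled drug's concept id.
#' @slot perSource named list: provenance tag -> data.frame(predicate,
#'   value, direction).
#' @slot perClass named list: core class (or "unclassified") ->
#'   data.frame(predicate, value, direction).
#' @export
setClass("FeatureProfile",
  representation(drug = "character", perSource = "list", perClass = "list"))

#' SimParams: parameters of the synthetic-source generator
#'
#' @slot nDrugs,nEnzymes,nTransporters counts of entities.
#' @slot nFeatureValues named integer: candidate feature values per
#'   similarity level.
#' @slot pInhibits,pInduces,pSubstrate,pFeature background fact
#'   probabilities in `[0, 1]`.
#' @slot nPlanted number of planted DDI pairs.
#' @slot seed integer RNG seed.
#' @export
setClass("SimParams",
  representation(nDrugs = "integer", nEnzymes = "integer",
                 nTransporters = "integer", nFeatureValues = "integer",
                 pInhibits = "numeric", pInduces = "numeric",
                 pSubstrate = "numeric", pFeature = "numeric",
                 nPlanted = "integer", seed = "integer"))

setValidity("SimParams", function(object) {
  p <- c(object@pInhibits, object@pInduces, object@pSubstrate, object@pFeature)
  if (any(p < 0 | p > 1)) return("probabilities must lie in [0, 1]")
  if (any(c(object@nDrugs, object@nEnzymes, object@nTransporters,
            object@nFeatureValues, object@nPlanted) < 0L))
    return("counts must be non-negative")
  if (object@nPlanted > object@nDrugs %/% 2L)
    return("nPlanted exceeds the number of disjoint drug pairs")
  if (object@nPlanted > 0L && object@nEnzymes + object@nTransporters == 0L)
    return("planting requires at least one enzyme or transporter")
  TRUE
})
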