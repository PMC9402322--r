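#' Accessors for mechkg classes
#'
#' Small generic accessor family: `triples()` and `entities()` expose
#' a graph's contents, `nTriples()`/`nEntities()` their sizes,
#' `rules()` and `theta()` a rule base's parts, `verdict()`,
#' `mechanismMatches()`, `featureMatches()` and `sharedLevelCount()`
#' the parts of a DDI assessment, `violations()` and `isConsistent()`
#' the parts of a consistency report, and `proofs()`/`status()` the
#' parts of a proof result.
#'
#' @param x the object.
#' @return the corresponding slot value (data frames, lists or
#'   scalars; never a reference into package internals).
#' @name accessors
#' @aliases triples entities nTriples nEntities rules theta verdict
#'   mechanismMatches featureMatches sharedLevelCount violations
#'   isConsistent proofs status
#' @examples
#' g <- addTriple(emptyGraph(), "C0000001", "inhibits", "C0000002")
#' nTriples(g)
#' triples(g)
NULL

#' @rdname accessors
#' @export
setGeneric("triples", function(x) standardGeneric("triples"))
#' @rdname accessors
#' @export
setGeneric("entities", function(x) standardGeneric("entities"))
#' @rdname accessors
#' @export
setGeneric("nTriples", function(x) standardGeneric("nTriples"))
#' @rdname accessors
#' @export
setGeneric("nEntities", function(x) standardGeneric("nEntities"))
#' @rdname accessors
#' @export
setGeneric("rules", function(x) standardGeneric("rules"))
#' @rdname accessors
#' @export
setGeneric("theta", function(x) standardGeneric("theta"))
#' @rdname accessors
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))
#' @rdname accessors
#' @export
setGeneric("mechanismMatches", function(x) standardGeneric("mechanismMatches"))
#' @rdname accessors
#' @export
setGeneric("featureMatches", function(x) standardGeneric("featureMatches"))
#' @rdname accessors
#' @export
setGeneric("sharedLevelCount", function(x) standardGeneric("sharedLevelCount"))
#' @rdname accessors
#' @export
setGeneric("violations", function(x) standardGeneric("violations"))
#' @rdname accessors
#' @export
setGeneric("isConsistent", function(x) standardGeneric("isConsistent"))
#' @rdname accessors
#' @export
setGeneric("proofs", function(x) standardGeneric("proofs"))
#' @rdname accessors
#' @export
setGeneric("status", function(x) standardGeneric("status"))

setMethod("triples", "KnowledgeGraph", function(x) x@triples)
setMethod("entities", "KnowledgeGraph", function(x) x@entities)
setMethod("nTriples", "KnowledgeGraph", function(x) nrow(x@triples))
setMethod("nEntities", "KnowledgeGraph", function(x) length(x@entities))
setMethod("rules", "RuleBase", function(x) x@rules)
setMethod("theta", "RuleBase", function(x) x@theta)
setMethod("verdict", "DDIAssessment", function(x) x@verdict)
setMethod("mechanismMatches", "DDIAssessment", function(x) x@mechanismMatches)
setMethod("featureMatches", "DDIAssessment", function(x) x@featureMatches)
setMethod("sharedLevelCount", "DDIAssessment", function(x) x@sharedLevelCount)
setMethod("violations", "ConsistencyReport", function(x) x@violations)
setMethod("isConsistent", "ConsistencyReport", function(x) x@isConsistent)
setMethod("proofs", "ProofResult", function(x) x@proofs)
setMethod("status", "ProofResult", function(x) x@status)

setMethod("show", "KnowledgeGraph", function(object) {
  cat(sprintf("KnowledgeGraph: %d triples over %d entities\n",
              nrow(object@triples), length(object@entities)))
  pr <- table(object@triples$provenance)
  if (length(pr) > 0L)
    cat("  provenance:", paste(sprintf("%s=%d", names(pr), as.integer(pr)),
                               collapse = ", "), "\n")
})

setMethod("show", "Schema", function(object) {
  cat(sprintf("Schema: %d core classes, %d subclasses, %d semantic-type mappings\n",
              length(object@coreClasses), length(object@subclasses),
              length(object@semtypeMap)))
  for (cc in object@coreClasses) {
    subs <- names(object@subclasses)[object@subclasses == cc]
    cat(sprintf("  %s: %s\n", cc, paste(subs, collapse = ", ")))
  }
})

setMethod("show", "RuleBase", function(object) {
  cat(sprintf("RuleBase: %d rules (theta = %g)\n",
              length(object@rules), object@theta))
  for (r in object@rules)
    cat(sprintf("  [%s] layer %d: %s :- %s\n", r@id, r@layer,
                deparseAtom(r@head),
                paste(vapply(r@body, deparseAtom, ""), collapse = ", ")))
})

setMethod("show", "ProofResult", function(object) {
  cat(sprintf("ProofResult: %s goal %s (%d proof%s)\n", object@status,
              deparseAtom(object@goal), length(object@proofs),
              if (length(object@proofs) == 1L) "" else "s"))
})

setMethod("show", "ConsistencyReport", function(object) {
  cat(sprintf("ConsistencyReport: %s (%d violations, %d warnings)\n",
              if (object@isConsistent) "consistent" else "INCONSISTENT",
              nrow(object@violations), nrow(object@warnings)))
})

setMethod("show", "DDIAssessment", function(object) {
  cat(sprintf("DDIAssessment: %s vs %s -> %s\n", object@drugA, object@drugB,
              object@verdict))
  cat(sprintf("  mechanism matches: %d; shared feature levels: %d (theta = %g)\n",
              length(object@mechanismMatches), object@sharedLevelCount,
              object@threshold))
})

setMethod("show", "MechanismMatch", function(object) {
  cat(sprintf("MechanismMatch [%s]: %s (%s) -> %s (%s); victim %s (substrate)\n",
              object@ruleId, object@perpetrator, object@perpetratorRole,
              object@target, object@targetKind, object@victim))
})
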