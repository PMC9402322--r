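## The six-rule, two-layer DDI framework: pharmacological-effect
## matching on metabolizing enzymes and transporters (layer 1),
## shared-biomedical-feature matching (layer 2), and the combination
## verdict.

#' The default six-rule DDI rule base
#'
#' Loads the shipped rule file (four layer-1 rules for enzyme /
#' transporter inhibition and induction, one layer-2 shared-feature
#' rule, one combination rule) with the shared-feature threshold
#' substituted into the combination rule's aggregate. The rules live
#' in a YAML config file, not in code, so they can be revised without
#' code changes; see [readRuleBase()] for the syntax.
#'
#' @param theta minimum number of distinct shared feature levels
#'   required alongside a mechanism match (default 1: any shared
#'   level suffices).
#' @return a [RuleBase-class] with exactly six rules.
#' @examples
#' length(rules(defaultRuleBase()))
#' @export
defaultRuleBase <- function(theta = 1) {
  readRuleBase(system.file("rules", "ddi_rules.yaml", package = "mechkg",
                           mustWork = TRUE), theta = theta)
}

RULE_TARGET_KIND <- c(R1 = "metabolizing_enzyme", R2 = "metabolizing_enzyme",
                      R3 = "transporter", R4 = "transporter")
ROLE_LABEL <- c(inhibition = "inhibitor", induction = "inducer")

assertDrugKnown <- function(graph, id) {
  if (!id %in% names(graph@entities))
    stop("unknown drug id: '", id, "'", call. = FALSE)
  invisible(id)
}

assertDistinctPair <- function(drugA, drugB) {
  if (identical(drugA, drugB))
    stop("a drug cannot be assessed against itself: '", drugA, "'",
         call. = FALSE)
  invisible(NULL)
}

#' Layer 1: pharmacological effects linking a drug pair
#'
#' All mechanism matches for the pair in both orientations: each
#' match names the perpetrator (the inhibitor or inducer), the victim
#' (the substrate), the enzyme or transporter target, the layer-1
#' rule that fired, and carries the proof tree.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param drugA,drugB drug concept ids (must exist in the graph).
#' @param rulebase a [RuleBase-class].
#' @param registry predicate registry.
#' @return list of [MechanismMatch-class], deterministically ordered
#'   by (target, perpetrator, rule).
#' @export
pharmacologicalEffects <- function(graph, drugA, drugB,
                                   rulebase = defaultRuleBase(),
                                   registry = defaultPredicateRegistry()) {
  assertDrugKnown(graph, drugA)
  assertDrugKnown(graph, drugB)
  assertDistinctPair(drugA, drugB)
  out <- list()
  for (pv in list(c(drugA, drugB), c(drugB, drugA))) {
    goal <- sprintf("mech(%s, %s, ?t, ?r)", pv[[1L]], pv[[2L]])
    res <- backwardChain(graph, rulebase, goal, registry = registry)
    if (res@status != "ACCEPTED") next
    ruleById <- stats::setNames(rulebase@rules,
                                vapply(rulebase@rules, function(r) r@id, ""))
    for (pf in res@proofs) {
      if (!identical(pf$type, "rule")) next
      b <- pf$bindings
      ## the interaction flavor is the (constant) fourth head
      ## argument of the layer-1 rule that fired
      headArgs <- ruleById[[pf$rule]]@head$args
      role <- if (isVar(headArgs[[4L]]))
        b[[sub("^\\?", "", headArgs[[4L]])]] else headArgs[[4L]]
      out[[length(out) + 1L]] <- new("MechanismMatch",
        target = b$t, targetKind = RULE_TARGET_KIND[[pf$rule]],
        perpetrator = pv[[1L]],
        perpetratorRole = ROLE_LABEL[[role]],
        victim = pv[[2L]], ruleId = pf$rule, proof = pf)
    }
  }
  key <- vapply(out, function(m)
    paste(m@target, m@perpetrator, m@ruleId, sep = "\r"), "")
  out <- out[!duplicated(key)]
  out[lexOrder(vapply(out, function(m)
    paste(m@target, m@perpetrator, m@ruleId, sep = "\r"), ""))]
}

#' Layer 2: biomedical features shared by a drug pair
#'
#' All shared-feature matches, grouped by similarity level, and the
#' number of distinct levels matched. Levels are the four ontology
#' core levels plus `substructure` and `contraindication`.
#'
#' @inheritParams pharmacologicalEffects
#' @return list with `matches` (list of [FeatureMatch-class],
#'   ordered by level then value) and `sharedLevelCount` (integer).
#' @export
sharedFeatures <- function(graph, drugA, drugB,
                           rulebase = defaultRuleBase(),
                           registry = defaultPredicateRegistry()) {
  assertDrugKnown(graph, drugA)
  assertDrugKnown(graph, drugB)
  assertDistinctPair(drugA, drugB)
  goal <- sprintf("shared(%s, %s, ?l, ?v)", drugA, drugB)
  res <- backwardChain(graph, rulebase, goal, registry = registry,
                       maxProofs = 10000L)
  matches <- list()
  if (res@status == "ACCEPTED") {
    for (pf in res@proofs) {
      if (!identical(pf$type, "rule")) next
      evidence <- Filter(function(n) identical(n$type, "fact"),
                         pf$children)
      matches[[length(matches) + 1L]] <- new("FeatureMatch",
        level = pf$bindings$l, value = pf$bindings$v,
        evidence = lapply(evidence, `[[`, "triple"))
    }
  }
  key <- vapply(matches, function(m) paste(m@level, m@value, sep = "\r"), "")
  matches <- matches[!duplicated(key)]
  matches <- matches[lexOrder(vapply(matches, function(m)
    paste(m@level, m@value, sep = "\r"), ""))]
  levels <- unique(vapply(matches, function(m) m@level, ""))
  list(matches = matches, sharedLevelCount = length(levels))
}

#' Assess a drug pair for a potential DDI
#'
#' Runs the combination goal `potential_ddi(drugA, drugB)` by
#' backward chaining, plus both layers for the evidence lists. The
#' verdict is `POTENTIAL_DDI` exactly when at least one mechanism
#' match exists (in either orientation) and the number of distinct
#' shared feature levels reaches `theta`; otherwise `NO_EVIDENCE`.
#' Assessments are symmetric up to role labeling: `assessDDI(g, a,
#' b)` and `assessDDI(g, b, a)` contain the same match sets.
#'
#' @inheritParams pharmacologicalEffects
#' @param theta shared-level threshold (>= 0); used to build the
#'   default rule base, ignored when `rulebase` is supplied.
#' @param rulebase optional pre-built [RuleBase-class] (its own
#'   threshold applies).
#' @return a [DDIAssessment-class].
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' fx <- canonicalFixture(dir)
#' g <- buildGraphFromFiles(fx$files[["mrconso"]], fx$files[["mrrel"]],
#'                          fx$files[["mrsat"]], fx$files[["links"]])$graph
#' a <- assessDDI(g, fx$drugs[["irinotecan"]], fx$drugs[["levofloxacin"]])
#' verdict(a)
#' @export
assessDDI <- function(graph, drugA, drugB, theta = 1, rulebase = NULL,
                      registry = defaultPredicateRegistry()) {
  stopifnot(theta >= 0)
  assertDrugKnown(graph, drugA)
  assertDrugKnown(graph, drugB)
  assertDistinctPair(drugA, drugB)
  rb <- rulebase %||% defaultRuleBase(theta = theta)
  goal <- sprintf("potential_ddi(%s, %s)", drugA, drugB)
  res <- backwardChain(graph, rb, goal, registry = registry)
  mech <- pharmacologicalEffects(graph, drugA, drugB, rulebase = rb,
                                 registry = registry)
  feat <- sharedFeatures(graph, drugA, drugB, rulebase = rb,
                         registry = registry)
  nLevels <- feat$sharedLevelCount
  v <- if (length(mech) > 0L && nLevels >= rb@theta) "POTENTIAL_DDI"
       else "NO_EVIDENCE"
  rationale <- character()
  for (m in mech) {
    flavor <- if (m@perpetratorRole == "inhibitor")
      "increased exposure expected" else "reduced exposure expected"
    rationale <- c(rationale, sprintf(
      "%s acts as %s of %s (%s); %s is a substrate of %s (%s): %s.",
      m@perpetrator, m@perpetratorRole, m@target, m@targetKind,
      m@victim, m@target, m@ruleId, flavor))
  }
  levels <- unique(vapply(feat$matches, function(m) m@level, ""))
  if (nLevels > 0L)
    rationale <- c(rationale, sprintf(
      "Shared biomedical features at %d level%s: %s.", nLevels,
      if (nLevels == 1L) "" else "s", paste(levels, collapse = ", ")))
  rationale <- c(rationale, sprintf(
    "Verdict: %s (mechanism matches: %d; shared levels: %d; threshold: %g).",
    v, length(mech), nLevels, rb@theta))
  new("DDIAssessment", drugA = drugA, drugB = drugB,
      threshold = rb@theta, mechanismMatches = mech,
      featureMatches = feat$matches, sharedLevelCount = nLevels,
      verdict = v, rationale = rationale,
      proof = if (res@status == "ACCEPTED") res@proofs else list())
}

#' Rank candidate drug pairs by strength of DDI evidence
#'
#' Assesses every candidate pair and orders the results: pairs with a
#' `POTENTIAL_DDI` verdict first, sorted by shared level count, then
#' number of feature matches, then number of mechanism matches (all
#' descending), with residual ties broken lexicographically on the
#' pair ids -- a deterministic total order.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param pairs a two-column data.frame (or list of length-2
#'   character vectors) of drug id pairs.
#' @param theta shared-level threshold.
#' @param rulebase optional pre-built [RuleBase-class].
#' @param registry predicate registry.
#' @return list of [DDIAssessment-class] in rank order.
#' @export
rankPairs <- function(graph, pairs, theta = 1, rulebase = NULL,
                      registry = defaultPredicateRegistry()) {
  rb <- rulebase %||% defaultRuleBase(theta = theta)
  if (is.data.frame(pairs))
    pairs <- lapply(seq_len(nrow(pairs)), function(i)
      c(pairs[[1L]][[i]], pairs[[2L]][[i]]))
  out <- lapply(pairs, function(p)
    assessDDI(graph, p[[1L]], p[[2L]], rulebase = rb,
              registry = registry))
  if (length(out) <= 1L) return(out)
  keyNum <- vapply(out, function(a) {
    c(a@verdict == "POTENTIAL_DDI", a@sharedLevelCount,
      length(a@featureMatches), length(a@mechanismMatches))
  }, numeric(4L))
  pairId <- vapply(out, function(a) paste(a@drugA, a@drugB, sep = "\r"), "")
  out[order(-keyNum[1L, ], -keyNum[2L, ], -keyNum[3L, ], -keyNum[4L, ],
            pairId, method = "radix")]
}
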