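## The rule language. Atoms are written in a one-line syntax:
##   relation atom:  pred(?a, C0000001, literal value)
##   builtin neq:    neq(?a, ?b)            (disequality; args ground)
##   builtin pair:   pair(?x, ?y, ?a, ?b)   (enumerates both orderings
##                                           of the ground pair x,y)
##   aggregate:      countd(?l, shared(?a, ?b, ?l, ?v)) >= 1
##                   (distinct ?l over solutions of the inner atom;
##                   only monotone comparisons >= and > are allowed,
##                   which keeps fixpoint semantics sound)
## Variables carry a leading "?"; everything else is a constant.
## Arguments may not contain commas or parentheses; feature literals
## with spaces are fine.

parseAtom <- function(text) {
  text <- trimws(text)
  agg <- regmatches(text, regexec(
    "^countd\\(\\s*(\\?[A-Za-z0-9_]+)\\s*,\\s*(.+\\))\\s*\\)\\s*(>=|>)\\s*([0-9.]+|\\{theta\\})\\s*$",
    text))[[1L]]
  if (length(agg) == 5L) {
    return(list(kind = "countd", var = agg[[2L]],
                inner = parseAtom(agg[[3L]]), op = agg[[4L]],
                k = agg[[5L]]))
  }
  m <- regmatches(text, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\((.*)\\)$",
                                text))[[1L]]
  if (length(m) != 3L) stop("malformed atom: ", text, call. = FALSE)
  pred <- m[[2L]]
  args <- trimws(strsplit(m[[3L]], ",", fixed = TRUE)[[1L]])
  if (any(!nzchar(args))) stop("empty argument in atom: ", text, call. = FALSE)
  if (pred == "neq") {
    if (length(args) != 2L) stop("neq takes 2 arguments", call. = FALSE)
    return(list(kind = "neq", args = args))
  }
  if (pred == "pair") {
    if (length(args) != 4L) stop("pair takes 4 arguments", call. = FALSE)
    return(list(kind = "pair", args = args))
  }
  list(kind = "rel", pred = pred, args = args)
}

deparseAtom <- function(atom) {
  switch(atom$kind,
    rel = sprintf("%s(%s)", atom$pred, paste(atom$args, collapse = ", ")),
    neq = sprintf("neq(%s)", paste(atom$args, collapse = ", ")),
    pair = sprintf("pair(%s)", paste(atom$args, collapse = ", ")),
    countd = sprintf("countd(%s, %s) %s %s", atom$var,
                     deparseAtom(atom$inner), atom$op, atom$k))
}

atomVars <- function(atom) {
  switch(atom$kind,
    rel = ,
    neq = ,
    pair = atom$args[vapply(atom$args, isVar, TRUE)],
    countd = setdiff(atomVars(atom$inner), atom$var))
}

## Variables an atom can *bind* (contribute to the substitution).
atomBinds <- function(atom) {
  switch(atom$kind,
    rel = atomVars(atom),
    pair = atom$args[3:4][vapply(atom$args[3:4], isVar, TRUE)],
    character())
}

## Variables an atom needs ground before it can be evaluated.
atomNeeds <- function(atom) {
  switch(atom$kind,
    rel = character(),
    neq = atomVars(atom),
    pair = atom$args[1:2][vapply(atom$args[1:2], isVar, TRUE)],
    countd = atomVars(atom))
}

#' Construct and validate a Horn rule
#'
#' Validation enforces range restriction (every head variable bound
#' by the body), left-to-right evaluability of builtins (their
#' required variables are bound by earlier atoms), and a non-empty
#' body.
#'
#' @param id rule identifier.
#' @param layer integer layer tag (1 pharmacological-effect, 2
#'   shared-feature, 3 combination).
#' @param head head atom, as text (see the rule syntax in
#'   [readRuleBase()]).
#' @param body character vector of body atoms, in evaluation order.
#' @return a [Rule-class].
#' @export
makeRule <- function(id, layer, head, body) {
  h <- parseAtom(head)
  if (h$kind != "rel")
    stop(sprintf("rule %s: head must be a relation atom", id), call. = FALSE)
  if (length(body) == 0L)
    stop(sprintf("rule %s: body must be non-empty", id), call. = FALSE)
  b <- lapply(body, parseAtom)
  bound <- character()
  for (j in seq_along(b)) {
    need <- atomNeeds(b[[j]])
    if (b[[j]]$kind == "countd") {
      ## inner variables not mentioned elsewhere in the rule are local
      ## existentials of the aggregate, not obligations
      elsewhere <- unique(c(atomVars(h),
                            unlist(lapply(b[-j], atomVars))))
      need <- intersect(need, elsewhere)
    }
    need <- setdiff(need, bound)
    if (length(need) > 0L)
      stop(sprintf("rule %s: builtin '%s' uses unbound variable %s",
                   id, deparseAtom(b[[j]]), need[[1L]]), call. = FALSE)
    bound <- union(bound, atomBinds(b[[j]]))
  }
  free <- setdiff(atomVars(h), bound)
  if (length(free) > 0L)
    stop(sprintf("rule %s is not range-restricted: head variable %s unbound",
                 id, free[[1L]]), call. = FALSE)
  new("Rule", id = as.character(id), layer = as.integer(layer),
      head = h, body = b)
}

headPred <- function(rule) rule@head$pred

rulePreds <- function(rulebase)
  unique(vapply(rulebase@rules, headPred, ""))

## Derived predicates referenced in a rule body (including aggregate
## inners).
bodyDerivedPreds <- function(rule, derived) {
  preds <- character()
  for (a in rule@body) {
    if (a$kind == "rel" && a$pred %in% derived)
      preds <- c(preds, a$pred)
    if (a$kind == "countd" && a$inner$kind == "rel" &&
        a$inner$pred %in% derived)
      preds <- c(preds, a$inner$pred)
  }
  unique(preds)
}

newRuleBase <- function(ruleList, theta = 1) {
  rb <- new("RuleBase", rules = ruleList, theta = as.numeric(theta))
  ## aggregates must be stratified: an aggregate's inner predicate may
  ## not depend (transitively) on the aggregating rule's own head
  derived <- rulePreds(rb)
  dep <- lapply(rb@rules, bodyDerivedPreds, derived = derived)
  names(dep) <- vapply(rb@rules, headPred, "")
  reach <- function(p) {
    seen <- character()
    todo <- p
    while (length(todo) > 0L) {
      q <- todo[[1L]]; todo <- todo[-1L]
      if (q %in% seen) next
      seen <- c(seen, q)
      todo <- c(todo, unlist(dep[names(dep) == q], use.names = FALSE))
    }
    seen
  }
  for (r in rb@rules) {
    for (a in r@body) {
      if (a$kind == "countd" && a$inner$kind == "rel" &&
          a$inner$pred %in% derived &&
          headPred(r) %in% reach(a$inner$pred))
        stop(sprintf("rule %s: aggregate over '%s' is recursive with its own head",
                     r@id, a$inner$pred), call. = FALSE)
    }
  }
  rb
}

#' Read a rule base from a YAML file
#'
#' The file is a YAML list of `{id, layer, head, body}` entries using
#' the one-line atom syntax, e.g.
#' \preformatted{
#' - id: R1
#'   layer: 1
#'   head: "mech(?a, ?b, ?t, inhibition)"
#'   body:
#'     - "inhibits(?a, ?t)"
#'     - "substrate_of(?b, ?t)"
#'     - "has_role(?t, metabolizing_enzyme)"
#'     - "neq(?a, ?b)"
#' }
#' The token `{theta}` inside an aggregate comparison is substituted
#' with the `theta` argument, so thresholds live in the rule file
#' rather than in code. Non-range-restricted rules are rejected here,
#' at load time.
#'
#' @param path YAML file path.
#' @param theta numeric threshold substituted for `{theta}`.
#' @return a [RuleBase-class].
#' @export
readRuleBase <- function(path, theta = 1) {
  spec <- yaml::read_yaml(path)
  rl <- lapply(spec, function(r)
    makeRule(r$id, r$layer, r$head, unlist(r$body)))
  rl <- lapply(rl, substituteTheta, theta = theta)
  newRuleBase(rl, theta = theta)
}

substituteTheta <- function(rule, theta) {
  rule@body <- lapply(rule@body, function(a) {
    if (a$kind == "countd" && identical(a$k, "{theta}")) a$k <- theta
    if (a$kind == "countd") a$k <- as.numeric(a$k)
    a
  })
  rule
}
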