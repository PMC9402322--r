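## The inference engines.
##
## backwardChain() is the query engine: goal-directed, tabled
## (memoized) evaluation restricted to the rules reachable from the
## goal's predicate, with proof-tree extraction. Tabling guarantees
## termination on recursive rule sets (finitely many constants, no
## function symbols). forwardClosure() is an independently coded
## bottom-up least-fixpoint engine, used throughout the test suite as
## the soundness/completeness oracle for the backward chainer.
##
## Facts are the graph's binary triples plus the virtual ternary view
##   feature(drug, level, value)
## expanded from the registered feature predicates. Derived facts of
## arity > 2 are encoded as triples by joining the trailing arguments
## with ";" (escaped inside arguments), so a closed graph can be fed
## back to either engine without loss.

ARG_SEP <- ";"

encodeArgs <- function(args) paste(gsub(";", "%3B", args, fixed = TRUE),
                                   collapse = ARG_SEP)

decodeArgs <- function(x) gsub("%3B", ";",
                               strsplit(x, ARG_SEP, fixed = TRUE)[[1L]],
                               fixed = TRUE)

derivedArities <- function(rulebase) {
  out <- integer()
  for (r in rulebase@rules) out[[headPred(r)]] <- length(r@head$args)
  out
}

## ---- fact tables -------------------------------------------------------

## Fact tables and binding sets are character matrices (bindings
## carry one column per variable, named with the leading "?"); this
## keeps the inner join loops free of data-frame overhead.

argMat <- function(k) matrix(character(), ncol = k)

rowKeys <- function(m) {
  if (ncol(m) == 0L) return(rep("", nrow(m)))
  if (ncol(m) == 1L) return(m[, 1L])
  do.call(paste, c(lapply(seq_len(ncol(m)), function(j) m[, j]),
                   sep = "\r"))
}

dedupRows <- function(m) {
  if (nrow(m) < 2L) return(m)
  k <- rowKeys(m)
  if (anyDuplicated(k)) m[!duplicated(k), , drop = FALSE] else m
}

sortRows <- function(m) {
  if (nrow(m) < 2L || ncol(m) == 0L) return(m)
  m[order(rowKeys(m), method = "radix"), , drop = FALSE]
}

## All facts for `pred` held by the graph itself (not the tables):
## character matrix with one column per argument.
graphFacts <- function(graph, pred, registry, arities) {
  tr <- graph@triples
  if (pred == "feature") {
    lv <- stats::setNames(registry$featureLevel, registry$predicate)
    sel <- tr$predicate %in% registry$predicate[!is.na(registry$featureLevel)]
    t2 <- tr[sel, , drop = FALSE]
    if (nrow(t2) == 0L) return(argMat(3L))
    return(dedupRows(cbind(t2$subject, unname(lv[t2$predicate]),
                           t2$object)))
  }
  sel <- tr$predicate == pred
  t2 <- tr[sel, , drop = FALSE]
  k <- if (pred %in% names(arities)) arities[[pred]] else 2L
  if (nrow(t2) == 0L) return(argMat(k))
  if (k == 2L) return(dedupRows(cbind(t2$subject, t2$object)))
  rest <- lapply(t2$object, decodeArgs)
  ok <- lengths(rest) == k - 1L
  rest <- rest[ok]
  if (length(rest) == 0L) return(argMat(k))
  dedupRows(cbind(t2$subject[ok], do.call(rbind, rest)))
}

## ---- tabled, goal-directed evaluation (backward chaining) --------------

newEngineState <- function(graph, rulebase, registry) {
  arities <- derivedArities(rulebase)
  tables <- list()
  for (p in names(arities))
    tables[[p]] <- graphFacts(graph, p, registry, arities)
  list(graph = graph, rulebase = rulebase, registry = registry,
       arities = arities, tables = tables,
       cache = new.env(parent = emptyenv()))
}

stateFacts <- function(state, pred) {
  if (pred %in% names(state$tables)) return(state$tables[[pred]])
  ## base fact tables never change during a query: memoize
  if (!is.null(state$cache) &&
      exists(pred, envir = state$cache, inherits = FALSE))
    return(get(pred, envir = state$cache, inherits = FALSE))
  out <- graphFacts(state$graph, pred, state$registry, state$arities)
  if (!is.null(state$cache)) assign(pred, out, envir = state$cache)
  out
}

## Natural (hash) join of two binding matrices.
joinBindings <- function(B, C) {
  if (ncol(B) == 0L) return(if (nrow(B) > 0L) C else C[0L, , drop = FALSE])
  if (ncol(C) == 0L) return(if (nrow(C) > 0L) B else B[0L, , drop = FALSE])
  common <- intersect(colnames(B), colnames(C))
  if (length(common) == 0L) {
    ib <- rep(seq_len(nrow(B)), times = nrow(C))
    ic <- rep(seq_len(nrow(C)), each = nrow(B))
    return(dedupRows(cbind(B[ib, , drop = FALSE], C[ic, , drop = FALSE])))
  }
  kc <- rowKeys(C[, common, drop = FALSE])
  kb <- rowKeys(B[, common, drop = FALSE])
  idx <- split(seq_len(nrow(C)), kc)
  hits <- idx[kb]
  ib <- rep(seq_len(nrow(B)), lengths(hits))
  ic <- unlist(hits, use.names = FALSE)
  extra <- setdiff(colnames(C), common)
  dedupRows(cbind(B[ib, , drop = FALSE],
                  C[ic, extra, drop = FALSE]))
}

## Join the current bindings B against the fact table of a relation
## atom.
evalRelAtom <- function(atom, B, state) {
  C <- stateFacts(state, atom$pred)
  if (ncol(C) != length(atom$args))
    return(B[0L, , drop = FALSE])
  seen <- character()
  keepCols <- integer()
  for (i in seq_along(atom$args)) {
    a <- atom$args[[i]]
    if (!isVar(a)) {
      C <- C[C[, i] == a, , drop = FALSE]
    } else if (a %in% seen) {
      first <- keepCols[match(a, seen)]
      C <- C[C[, first] == C[, i], , drop = FALSE]
    } else {
      seen <- c(seen, a)
      keepCols <- c(keepCols, i)
    }
  }
  if (length(keepCols) == 0L) {
    ## membership test: succeeds (without binding) iff a fact matched
    return(if (nrow(C) > 0L) B else B[0L, , drop = FALSE])
  }
  C <- C[, keepCols, drop = FALSE]
  colnames(C) <- seen
  joinBindings(B, dedupRows(C))
}

valueOf <- function(term, B) if (isVar(term)) B[, term] else
  rep(term, nrow(B))

evalBuiltin <- function(atom, B, state) {
  if (nrow(B) == 0L) return(B)
  if (atom$kind == "neq") {
    x <- valueOf(atom$args[[1L]], B)
    y <- valueOf(atom$args[[2L]], B)
    return(B[x != y, , drop = FALSE])
  }
  if (atom$kind == "pair") {
    x <- valueOf(atom$args[[1L]], B)
    y <- valueOf(atom$args[[2L]], B)
    out <- list()
    for (ord in 1:2) {
      a <- if (ord == 1L) x else y
      b <- if (ord == 1L) y else x
      Bi <- B
      keep <- rep(TRUE, nrow(Bi))
      for (j in 3:4) {
        t <- atom$args[[j]]
        v <- if (j == 3L) a else b
        if (isVar(t)) {
          if (t %in% colnames(Bi)) keep <- keep & Bi[, t] == v
          else {
            Bi <- cbind(Bi, v)
            colnames(Bi)[ncol(Bi)] <- t
          }
        } else keep <- keep & v == t
      }
      out[[ord]] <- Bi[keep, , drop = FALSE]
    }
    return(dedupRows(rbind(out[[1L]], out[[2L]])))
  }
  if (atom$kind == "countd") {
    keep <- logical(nrow(B))
    for (i in seq_len(nrow(B))) {
      inst <- atom$inner
      inst$args <- vapply(inst$args, function(a) {
        if (isVar(a) && a %in% colnames(B) && a != atom$var) B[i, a] else a
      }, "")
      sol <- evalRelAtom(inst, unitBindings(), state)
      n <- if (atom$var %in% colnames(sol))
        length(unique(sol[, atom$var])) else nrow(sol)
      keep[[i]] <- if (atom$op == ">=") n >= atom$k else n > atom$k
    }
    return(B[keep, , drop = FALSE])
  }
  stop("unknown builtin kind: ", atom$kind, call. = FALSE)
}

unitBindings <- function() matrix(character(), nrow = 1L, ncol = 0L)

evalAtom <- function(atom, B, state) {
  if (atom$kind == "rel") evalRelAtom(atom, B, state)
  else evalBuiltin(atom, B, state)
}

evalRuleBody <- function(rule, B, state) {
  for (a in rule@body) {
    B <- evalAtom(a, B, state)
    if (nrow(B) == 0L) break
  }
  B
}

## One bottom-up pass of a single rule against the current tables;
## returns the updated state and whether new head tuples appeared.
applyRuleOnce <- function(rule, state) {
  B <- evalRuleBody(rule, unitBindings(), state)
  p <- headPred(rule)
  if (nrow(B) == 0L) return(list(state = state, changed = FALSE))
  k <- length(rule@head$args)
  new <- do.call(cbind, lapply(seq_len(k), function(i)
    valueOf(rule@head$args[[i]], B)))
  colnames(new) <- NULL
  cur <- state$tables[[p]]
  comb <- dedupRows(rbind(cur, new))
  changed <- nrow(comb) > nrow(cur)
  state$tables[[p]] <- comb
  list(state = state, changed = changed)
}

## Derived predicates reachable from `pred` through rule bodies
## (including aggregate inners): the goal's dependency cone, the only
## part of the program a query ever evaluates.
reachablePreds <- function(rulebase, pred) {
  derived <- rulePreds(rulebase)
  seen <- character()
  todo <- intersect(pred, derived)
  while (length(todo) > 0L) {
    p <- todo[[1L]]; todo <- todo[-1L]
    if (p %in% seen) next
    seen <- c(seen, p)
    for (r in rulebase@rules[vapply(rulebase@rules, headPred, "") == p])
      todo <- c(todo, bodyDerivedPreds(r, derived))
  }
  seen
}

saturate <- function(state, preds) {
  sel <- vapply(state$rulebase@rules, function(r) headPred(r) %in% preds,
                TRUE)
  rulesToRun <- state$rulebase@rules[sel]
  repeat {
    changed <- FALSE
    for (r in rulesToRun) {
      res <- applyRuleOnce(r, state)
      state <- res$state
      changed <- changed || res$changed
    }
    if (!changed) break
  }
  state
}

#' Prove or reject a goal by backward chaining
#'
#' Goal-directed, tabled evaluation: only the rules in the goal
#' predicate's dependency cone are evaluated, answers are memoized in
#' per-predicate tables, and evaluation runs to a local fixpoint, so
#' recursive rule sets terminate. The engine is sound and complete
#' with respect to the least Horn model of the graph and rules: a
#' ground goal is `ACCEPTED` exactly when it lies in the forward
#' closure (see [forwardClosure()], the independently coded oracle).
#'
#' All distinct minimal proofs are extracted (up to `maxProofs`),
#' deduplicated and deterministically ordered, so two runs on
#' identical inputs produce byte-identical serialized results.
#'
#' @param graph a [KnowledgeGraph-class].
#' @param rulebase a [RuleBase-class] (e.g. [defaultRuleBase()]).
#' @param goal the goal atom: a string like
#'   `"potential_ddi(C9000001, C9000002)"` (variables written `?x`),
#'   a parsed atom list, or a [triplePattern()] (interpreted as
#'   `predicate(subject, object)`).
#' @param registry predicate registry.
#' @param maxProofs cap on extracted proofs per answer.
#' @return a [ProofResult-class].
#' @examples
#' g <- addTriple(emptyGraph(), "C0000001", "inhibits", "C0000003")
#' g <- addTriple(g, "C0000002", "substrate_of", "C0000003")
#' g <- addTriple(g, "C0000003", "has_role", "metabolizing_enzyme")
#' r <- backwardChain(g, defaultRuleBase(),
#'                    "mech(?p, ?v, ?t, inhibition)")
#' status(r)
#' @export
backwardChain <- function(graph, rulebase, goal,
                          registry = defaultPredicateRegistry(),
                          maxProofs = 100L) {
  atom <- asGoalAtom(goal)
  state <- newEngineState(graph, rulebase, registry)
  reach <- reachablePreds(rulebase, atom$pred)
  if (length(reach) > 0L) state <- saturate(state, reach)
  B <- evalRelAtom(atom, unitBindings(), state)
  vars <- unique(atom$args[vapply(atom$args, isVar, TRUE)])
  bindings <- if (length(vars) == 0L) {
    data.frame(row.names = seq_len(min(nrow(B), 1L)))
  } else {
    m <- sortRows(dedupRows(B[, vars, drop = FALSE]))
    out <- as.data.frame(m, stringsAsFactors = FALSE)
    names(out) <- sub("^\\?", "", vars)
    rownames(out) <- NULL
    out
  }
  ## proofs: one set per ground instance of the goal
  instances <- if (length(vars) == 0L) {
    if (nrow(B) > 0L) list(atom$args) else list()
  } else {
    lapply(seq_len(nrow(bindings)), function(i) {
      vapply(atom$args, function(a) {
        if (isVar(a)) bindings[[sub("^\\?", "", a)]][[i]] else a
      }, "")
    })
  }
  proofList <- list()
  for (inst in instances) {
    pf <- proveAtom(state, atom$pred, inst, path = character(),
                    maxProofs = maxProofs)
    proofList <- c(proofList, pf)
    if (length(proofList) >= maxProofs) {
      proofList <- proofList[seq_len(maxProofs)]
      break
    }
  }
  proofList <- dedupProofs(proofList)
  new("ProofResult", goal = atom,
      status = if (length(proofList) > 0L) "ACCEPTED" else "REJECTED",
      bindings = bindings, proofs = proofList)
}

asGoalAtom <- function(goal) {
  if (is.character(goal)) return(parseAtom(goal))
  if (inherits(goal, "TriplePattern"))
    return(list(kind = "rel", pred = goal$predicate,
                args = c(goal$subject, goal$object)))
  stopifnot(is.list(goal), identical(goal$kind, "rel"))
  goal
}

#' Count distinct solutions of a pattern under the rule base
#'
#' The number of distinct variable bindings proving the atom; equals
#' the number of matching facts in the forward closure.
#'
#' @inheritParams backwardChain
#' @param pattern goal atom with variables (same forms as `goal` in
#'   [backwardChain()]).
#' @return integer count.
#' @export
countSolutions <- function(graph, rulebase, pattern,
                           registry = defaultPredicateRegistry()) {
  res <- backwardChain(graph, rulebase, pattern, registry = registry,
                       maxProofs = 1L)
  max(nrow(res@bindings), if (res@status == "ACCEPTED") 1L else 0L)
}

## ---- proof extraction --------------------------------------------------

proofKey <- function(node) {
  as.character(stableJSON(node, pretty = FALSE))
}

dedupProofs <- function(proofs) {
  if (length(proofs) == 0L) return(proofs)
  keys <- vapply(proofs, proofKey, "")
  proofs <- proofs[!duplicated(keys)]
  proofs[lexOrder(vapply(proofs, proofKey, ""))]
}

factLeaves <- function(state, pred, args) {
  tr <- state$graph@triples
  leaf <- function(i) list(
    type = "fact",
    triple = list(subject = tr$subject[[i]], predicate = tr$predicate[[i]],
                  object = tr$object[[i]],
                  provenance = tr$provenance[[i]]))
  if (pred == "feature") {
    preds <- predicatesForLevel(state$registry, args[[2L]])
    idx <- which(tr$subject == args[[1L]] & tr$predicate %in% preds &
                   tr$object == args[[3L]])
    return(lapply(idx, leaf))
  }
  if (length(args) == 2L) {
    idx <- which(tr$subject == args[[1L]] & tr$predicate == pred &
                   tr$object == args[[2L]])
    return(lapply(idx, leaf))
  }
  enc <- encodeArgs(args[-1L])
  idx <- which(tr$subject == args[[1L]] & tr$predicate == pred &
                 tr$object == enc)
  lapply(idx, leaf)
}

## All minimal distinct proofs of a ground atom against the saturated
## state. Distinct rule instantiations give distinct proofs; within
## one instantiation each body atom contributes its first proof.
## `path` blocks cyclic derivations, keeping proofs minimal and
## extraction terminating.
proveAtom <- function(state, pred, args, path, maxProofs) {
  key <- paste0(pred, "(", paste(args, collapse = ","), ")")
  out <- factLeaves(state, pred, args)
  if (key %in% path || length(out) >= maxProofs)
    return(out[seq_len(min(length(out), maxProofs))])
  path <- c(path, key)
  derived <- names(state$arities)
  if (pred %in% derived) {
    for (rule in state$rulebase@rules) {
      if (headPred(rule) != pred) next
      theta <- unifyHead(rule@head$args, args)
      if (is.null(theta)) next
      B <- bindingsFrame(theta)
      full <- sortRows(evalRuleBody(rule, B, state))
      if (nrow(full) == 0L) next
      for (i in seq_len(nrow(full))) {
        kids <- proveBodyRow(state, rule, full[i, ], path)
        if (is.null(kids)) next
        bind <- as.list(full[i, ])
        names(bind) <- sub("^\\?", "", colnames(full))
        out[[length(out) + 1L]] <- list(type = "rule", rule = rule@id,
                                        layer = rule@layer,
                                        bindings = bind[lexOrder(names(bind))],
                                        children = kids)
        if (length(out) >= maxProofs) return(dedupProofs(out))
      }
    }
  }
  dedupProofs(out)
}

unifyHead <- function(headArgs, args) {
  theta <- list()
  for (i in seq_along(headArgs)) {
    h <- headArgs[[i]]
    if (isVar(h)) {
      if (!is.null(theta[[h]]) && theta[[h]] != args[[i]]) return(NULL)
      theta[[h]] <- args[[i]]
    } else if (h != args[[i]]) return(NULL)
  }
  theta
}

bindingsFrame <- function(theta) {
  if (length(theta) == 0L) return(unitBindings())
  matrix(unlist(theta), nrow = 1L,
         dimnames = list(NULL, names(theta)))
}

## `row` is a named character vector (one matrix row).
instantiate <- function(args, row) {
  vapply(args, function(a) {
    if (isVar(a) && a %in% names(row)) row[[a]] else a
  }, "")
}

proveBodyRow <- function(state, rule, row, path) {
  kids <- list()
  for (a in rule@body) {
    if (a$kind == "rel") {
      inst <- instantiate(a$args, row)
      sub <- proveAtom(state, a$pred, inst, path, maxProofs = 1L)
      if (length(sub) == 0L) return(NULL)
      kids[[length(kids) + 1L]] <- sub[[1L]]
    } else if (a$kind %in% c("neq", "pair")) {
      kids[[length(kids) + 1L]] <-
        list(type = "builtin", builtin = a$kind,
             args = as.list(instantiate(a$args, row)))
    } else {   # countd
      inst <- a$inner
      inst$args <- vapply(inst$args, function(t) {
        if (isVar(t) && t %in% names(row) && t != a$var) row[[t]]
        else t
      }, "")
      sol <- evalRelAtom(inst, unitBindings(), state)
      vals <- if (a$var %in% colnames(sol))
        lexSort(unique(sol[, a$var])) else character()
      sub <- list()
      for (v in vals) {
        vinst <- inst
        vinst$args[vinst$args == a$var] <- v
        ## inner atoms may keep local existential variables (e.g. the
        ## shared value); take the first proof of each counted value
        p <- proveAtomPattern(state, vinst, path)
        if (!is.null(p)) sub[[length(sub) + 1L]] <- p
      }
      kids[[length(kids) + 1L]] <-
        list(type = "builtin", builtin = "countd",
             var = a$var, count = length(vals), op = a$op, k = a$k,
             children = sub)
    }
  }
  kids
}

## First proof of a possibly non-ground atom (existential variables
## are witness-bound by the first solution).
proveAtomPattern <- function(state, atom, path) {
  sol <- evalRelAtom(atom, unitBindings(), state)
  if (nrow(sol) == 0L) return(NULL)
  sol <- sortRows(sol)
  inst <- instantiate(atom$args, sol[1L, ])
  p <- proveAtom(state, atom$pred, inst, path, maxProofs = 1L)
  if (length(p) == 0L) NULL else p[[1L]]
}

#' Distinct rule layers used in a proof tree
#'
#' Collects the `layer` tags of every rule-application node in a
#' proof, by default excluding the combination layer (tag 3), so the
#' accepted proof of a DDI goal reports how many inference layers its
#' evidence spans.
#'
#' @param proof a proof tree (see [ProofResult-class]) or a
#'   [ProofResult-class] (its proofs are pooled).
#' @param excludeCombination drop layer-3 (combination) applications.
#' @return sorted integer vector of distinct layers.
#' @export
proofLayers <- function(proof, excludeCombination = TRUE) {
  if (is(proof, "ProofResult")) {
    out <- unlist(lapply(proof@proofs, proofLayers,
                         excludeCombination = excludeCombination))
    return(sort(unique(as.integer(out %||% integer()))))
  }
  acc <- integer()
  walk <- function(node) {
    if (identical(node$type, "rule")) {
      acc <<- c(acc, node$layer)
      lapply(node$children, walk)
    } else if (identical(node$type, "builtin") &&
               !is.null(node$children)) {
      lapply(node$children, walk)
    }
    invisible(NULL)
  }
  walk(proof)
  out <- sort(unique(acc))
  if (excludeCombination) out <- setdiff(out, 3L)
  as.integer(out)
}

## ---- forward closure (independent bottom-up oracle) --------------------

#' Forward closure: the least Horn model as a graph
#'
#' An independently implemented bottom-up engine: starting from the
#' graph's facts (plus the virtual `feature` view), rules are applied
#' naively -- one candidate substitution at a time, by textbook
#' unification -- until the least fixpoint. Inferred facts are added
#' as triples with provenance `INFERRED`; derived facts of arity > 2
#' encode their trailing arguments in the object (`;`-joined), so
#' `forwardClosure(forwardClosure(g, r), r)` equals
#' `forwardClosure(g, r)`.
#'
#' Termination is guaranteed (finite constants, no function symbols);
#' aggregates are restricted to monotone comparisons so the fixpoint
#' is well-defined. This engine exists as the correctness oracle for
#' [backwardChain()]; the two share no evaluation code.
#'
#' @inheritParams backwardChain
#' @return the input graph plus `INFERRED` triples.
#' @export
forwardClosure <- function(graph, rulebase,
                           registry = defaultPredicateRegistry()) {
  arities <- derivedArities(rulebase)
  ## derived fact store: pred -> environment keyed by encoded args
  store <- new.env(parent = emptyenv())
  for (p in names(arities)) assign(p, new.env(parent = emptyenv()),
                                   envir = store)
  seed <- function(p) {
    df <- graphFacts(graph, p, registry, arities)
    for (i in seq_len(nrow(df)))
      assign(encodeArgs(as.character(df[i, ])), TRUE,
             envir = get(p, envir = store))
  }
  for (p in names(arities)) seed(p)

  baseFactRows <- function(pred) {
    if (pred %in% names(arities)) {
      keys <- ls(get(pred, envir = store), sorted = TRUE)
      return(lapply(keys, decodeArgs))
    }
    df <- graphFacts(graph, pred, registry, arities)
    lapply(seq_len(nrow(df)), function(i) as.character(df[i, ]))
  }

  unify <- function(pat, fact, subst) {
    if (length(pat) != length(fact)) return(NULL)
    for (i in seq_along(pat)) {
      t <- pat[[i]]
      if (isVar(t)) {
        if (!is.null(subst[[t]])) {
          if (subst[[t]] != fact[[i]]) return(NULL)
        } else subst[[t]] <- fact[[i]]
      } else if (t != fact[[i]]) return(NULL)
    }
    subst
  }
  ground <- function(term, subst) if (isVar(term)) subst[[term]] else term

  solutionsOf <- function(atom, subst) {
    ## all extensions of subst satisfying a relation atom
    out <- list()
    for (fact in baseFactRows(atom$pred)) {
      s2 <- unify(atom$args, fact, subst)
      if (!is.null(s2)) out[[length(out) + 1L]] <- s2
    }
    out
  }

  added <- FALSE
  applyRule <- function(rule) {
    recur <- function(i, subst) {
      if (i > length(rule@body)) {
        vals <- vapply(rule@head$args, ground, "", subst = subst)
        env <- get(headPred(rule), envir = store)
        key <- encodeArgs(vals)
        if (!exists(key, envir = env, inherits = FALSE)) {
          assign(key, TRUE, envir = env)
          added <<- TRUE
        }
        return(invisible(NULL))
      }
      a <- rule@body[[i]]
      if (a$kind == "rel") {
        for (s2 in solutionsOf(a, subst)) recur(i + 1L, s2)
      } else if (a$kind == "neq") {
        v <- vapply(a$args, ground, "", subst = subst)
        if (v[[1L]] != v[[2L]]) recur(i + 1L, subst)
      } else if (a$kind == "pair") {
        x <- ground(a$args[[1L]], subst)
        y <- ground(a$args[[2L]], subst)
        for (ab in list(c(x, y), c(y, x))) {
          s2 <- unify(a$args[3:4], ab, subst)
          if (!is.null(s2)) recur(i + 1L, s2)
        }
      } else {   # countd
        inst <- a$inner
        inst$args <- vapply(inst$args, function(t) {
          if (isVar(t) && !is.null(subst[[t]]) && t != a$var)
            subst[[t]] else t
        }, "")
        sols <- solutionsOf(inst, list())
        n <- if (a$var %in% inst$args)
          length(unique(vapply(sols, function(s) s[[a$var]], "")))
        else length(sols)
        ok <- if (a$op == ">=") n >= a$k else n > a$k
        if (ok) recur(i + 1L, subst)
      }
      invisible(NULL)
    }
    recur(1L, list())
  }

  repeat {
    added <- FALSE
    for (r in rulebase@rules) applyRule(r)
    if (!added) break
  }

  out <- graph
  rows <- list()
  for (p in lexSort(names(arities))) {
    keys <- ls(get(p, envir = store), sorted = TRUE)
    for (key in keys) {
      args <- decodeArgs(key)
      if (length(args) == 2L) {
        if (hasFact(graph, args[[1L]], p, args[[2L]])) next
        rows[[length(rows) + 1L]] <-
          data.frame(subject = args[[1L]], predicate = p,
                     object = args[[2L]], literal = TRUE,
                     provenance = "INFERRED", stringsAsFactors = FALSE)
      } else {
        enc <- encodeArgs(args[-1L])
        if (hasFact(graph, args[[1L]], p, enc)) next
        rows[[length(rows) + 1L]] <-
          data.frame(subject = args[[1L]], predicate = p,
                     object = enc, literal = TRUE,
                     provenance = "INFERRED", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) > 0L)
    out <- addTriples(out, do.call(rbind, rows), registry = registry)
  out
}
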