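test_that("any goal on an empty graph is rejected", {
  r <- backwardChain(emptyGraph(), defaultRules(),
                     "potential_ddi(C0000001, C0000002)")
  expect_identical(status(r), "REJECTED")
  expect_length(proofs(r), 0L)
})

test_that("closure of an empty graph is empty, and closure is idempotent", {
  rb <- defaultRules()
  cl0 <- forwardClosure(emptyGraph(), rb)
  expect_equal(nTriples(cl0), 0L)
  g <- fixtureBundle()$graph
  cl <- forwardClosure(g, rb)
  expect_gt(nTriples(cl), nTriples(g))
  expect_identical(graphSignature(forwardClosure(cl, rb)),
                   graphSignature(cl))
})

test_that("backward chaining agrees with the forward-closure oracle", {
  rb <- defaultRules()
  drugs <- sprintf("C82%05d", 1:3)
  for (seed in 1:150) {
    g <- randomDdiGraph(seed)
    cl <- triples(forwardClosure(g, rb))
    for (a in drugs) for (b in drugs) {
      if (a == b) next
      acc <- status(backwardChain(
        g, rb, sprintf("potential_ddi(%s, %s)", a, b),
        maxProofs = 1L)) == "ACCEPTED"
      inferred <- any(cl$predicate == "potential_ddi" &
                        cl$subject == a & cl$object == b)
      expect_identical(acc, inferred,
                       info = sprintf("seed %d pair %s/%s", seed, a, b))
    }
    ## answer sets for open goals equal the closure's derived facts
    bm <- backwardChain(g, rb, "mech(?p, ?v, ?t, ?r)", maxProofs = 1L)
    mf <- cl[cl$predicate == "mech", , drop = FALSE]
    got <- sort(sprintf("%s;%s", bm@bindings$p,
                        paste(bm@bindings$v, bm@bindings$t, bm@bindings$r,
                              sep = ";")))
    expect_identical(got, sort(paste(mf$subject, mf$object, sep = ";")),
                     info = sprintf("seed %d mech set", seed))
  }
})

test_that("closure is monotone under fact addition", {
  rb <- defaultRules()
  for (seed in 1:20) {
    g2 <- randomDdiGraph(seed, nDrugs = 3L, nTargets = 2L)
    tr <- triples(g2)
    set.seed(seed + 1000)
    keep <- sort(sample(nrow(tr), max(1L, nrow(tr) %/% 2L)))
    g1 <- addTriples(emptyGraph(), tr[keep, , drop = FALSE])
    c1 <- triples(forwardClosure(g1, rb))
    c2 <- triples(forwardClosure(g2, rb))
    k1 <- paste(c1$subject, c1$predicate, c1$object, sep = "\r")
    k2 <- paste(c2$subject, c2$predicate, c2$object, sep = "\r")
    expect_true(all(k1 %in% k2), info = sprintf("seed %d", seed))
  }
})

test_that("adding facts never flips an accepted goal to rejected", {
  rb <- defaultRules()
  for (seed in 1:10) {
    g <- randomDdiGraph(seed)
    cl <- triples(forwardClosure(g, rb))
    pd <- cl[cl$predicate == "potential_ddi", , drop = FALSE]
    if (nrow(pd) == 0L) next
    goal <- sprintf("potential_ddi(%s, %s)", pd$subject[[1L]],
                    pd$object[[1L]])
    g2 <- addTriple(g, "C8299999", "has_effect", "C8700001")
    g2 <- addTriple(g2, pd$subject[[1L]], "has_effect", "C8700099")
    expect_identical(status(backwardChain(g2, rb, goal, maxProofs = 1L)),
                     "ACCEPTED")
  }
})

test_that("countSolutions equals matching on the forward closure", {
  rb <- defaultRules()
  for (seed in c(3, 7, 21)) {
    g <- randomDdiGraph(seed)
    cl <- triples(forwardClosure(g, rb))
    n <- countSolutions(g, rb, "shared(?a, ?b, ?l, ?v)")
    expect_equal(n, sum(cl$predicate == "shared"),
                 info = sprintf("seed %d", seed))
    expect_equal(countSolutions(g, rb,
                                "shared(C8299998, C8299997, ?l, ?v)"), 0L)
  }
})

test_that("non-range-restricted rules are rejected at load time", {
  expect_error(makeRule("bad1", 1L, "mech(?a, ?b, ?t, inhibition)",
                        c("inhibits(?a, ?t)")),
               "range-restricted")
  expect_error(makeRule("bad2", 1L, "shared(?a, ?b, ?l, ?v)",
                        character()),
               "non-empty")
  expect_error(makeRule("bad3", 1L, "mech(?a, ?b, ?t, x)",
                        c("neq(?a, ?b)", "inhibits(?a, ?t)",
                          "substrate_of(?b, ?t)")),
               "unbound")
})

test_that("recursive rule sets terminate and reach the full closure", {
  anc <- list(
    makeRule("A1", 1L, "ancestor_of(?x, ?y)", "parent_of(?x, ?y)"),
    makeRule("A2", 1L, "ancestor_of(?x, ?z)",
             c("parent_of(?x, ?y)", "ancestor_of(?y, ?z)")))
  rb <- new("RuleBase", rules = anc, theta = 1)
  g <- addTriple(emptyGraph(), "C0000001", "parent_of", "C0000002")
  g <- addTriple(g, "C0000002", "parent_of", "C0000003")
  g <- addTriple(g, "C0000003", "parent_of", "C0000001")  # cycle
  r <- backwardChain(g, rb, "ancestor_of(C0000001, ?z)")
  expect_identical(status(r), "ACCEPTED")
  expect_setequal(r@bindings$z, c("C0000001", "C0000002", "C0000003"))
  cl <- triples(forwardClosure(g, rb))
  expect_equal(sum(cl$predicate == "ancestor_of"), 9L)
})

test_that("proof results are byte-identical across runs", {
  g <- fixtureBundle()$graph
  rb <- defaultRules()
  goal <- "potential_ddi(C9000001, C9000002)"
  r1 <- backwardChain(g, rb, goal)
  r2 <- backwardChain(g, rb, goal)
  s1 <- jsonlite::toJSON(proofs(r1), auto_unbox = TRUE, digits = NA)
  s2 <- jsonlite::toJSON(proofs(r2), auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("proof trees ground out in graph facts and replay their goal", {
  g <- fixtureBundle()$graph
  rb <- defaultRules()
  r <- backwardChain(g, rb, "mech(C9000002, C9000001, C9000003, inhibition)")
  expect_identical(status(r), "ACCEPTED")
  leaves <- list()
  walk <- function(n) {
    if (identical(n$type, "fact")) leaves[[length(leaves) + 1L]] <<- n$triple
    for (k in c(n$children, if (identical(n$type, "builtin")) n$children))
      if (is.list(k)) walk(k)
    invisible(NULL)
  }
  walk(proofs(r)[[1L]])
  expect_gt(length(leaves), 0L)
  tr <- triples(g)
  for (lf in leaves) {
    expect_true(any(tr$subject == lf$subject &
                      tr$predicate == lf$predicate &
                      tr$object == lf$object),
                info = paste(unlist(lf), collapse = " "))
  }
})

test_that("aggregates recursive with their own head are rejected", {
  selfAgg <- makeRule("X1", 3L, "shared(?a, ?b, all, all)",
                      c("inhibits(?a, ?t)", "inhibits(?b, ?t)",
                        "neq(?a, ?b)",
                        "countd(?l, shared(?a, ?b, ?l, ?v)) >= 1"))
  selfAgg <- mechkg:::substituteTheta(selfAgg, 1)
  expect_error(mechkg:::newRuleBase(list(selfAgg), theta = 1),
               "recursive")
})
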