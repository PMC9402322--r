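test_that("the default rule base has six rules in the expected layers", {
  rb <- defaultRules()
  expect_length(rules(rb), 6L)
  layers <- vapply(rules(rb), function(r) r@layer, 1L)
  expect_equal(sum(layers == 1L), 4L)
  expect_equal(sum(layers == 2L), 1L)
  expect_equal(sum(layers == 3L), 1L)
  ## all loadable rules are range-restricted by construction: reparsing
  ## the shipped file succeeds
  expect_silent(readRuleBase(system.file("rules", "ddi_rules.yaml",
                                         package = "mechkg"), theta = 2))
})

test_that("the fixture pair yields the two expected mechanism matches", {
  b <- fixtureBundle()
  m <- pharmacologicalEffects(b$graph, "C9000001", "C9000002",
                              rulebase = defaultRules())
  expect_length(m, 2L)
  keys <- mechanismKeys(m)
  expect_identical(keys, sort(c(
    paste("C9000002", "C9000001", "C9000003", "inhibitor",
          "metabolizing_enzyme", sep = "\r"),
    paste("C9000002", "C9000001", "C9000004", "inhibitor",
          "transporter", sep = "\r"))))
  ## levofloxacin is the perpetrator in both; irinotecan the victim
  expect_true(all(vapply(m, function(x) x@perpetrator == "C9000002", TRUE)))
  expect_true(all(vapply(m, function(x) x@victim == "C9000001", TRUE)))
})

test_that("mechanism matches equal the brute-force enumeration oracle", {
  rb <- defaultRules()
  drugs <- sprintf("C82%05d", 1:3)
  for (seed in 1:40) {
    g <- randomDdiGraph(seed)
    for (i in 1:2) for (j in (i + 1):3) {
      got <- mechanismKeys(pharmacologicalEffects(
        g, drugs[[i]], drugs[[j]], rulebase = rb))
      want <- bruteMechanisms(g, drugs[[i]], drugs[[j]])
      expect_identical(got, want,
                       info = sprintf("seed %d pair %d-%d", seed, i, j))
    }
  }
})

test_that("drugs without shared targets yield no mechanism matches", {
  g <- addTriple(emptyGraph(), "C0000001", "inhibits", "C0000003")
  g <- addTriple(g, "C0000002", "substrate_of", "C0000004")
  g <- addTriple(g, "C0000003", "has_role", "metabolizing_enzyme")
  g <- addTriple(g, "C0000004", "has_role", "transporter")
  expect_length(pharmacologicalEffects(g, "C0000001", "C0000002",
                                       rulebase = defaultRules()), 0L)
})

test_that("unknown drugs and self-pairs are hard errors naming the id", {
  g <- fixtureBundle()$graph
  expect_error(pharmacologicalEffects(g, "C9999999", "C9000002",
                                      rulebase = defaultRules()),
               "C9999999")
  expect_error(assessDDI(g, "C9000001", "C9000001",
                         rulebase = defaultRules()), "itself")
})

test_that("the fixture pair shares features at exactly three levels", {
  b <- fixtureBundle()
  sf <- sharedFeatures(b$graph, "C9000001", "C9000002",
                       rulebase = defaultRules())
  expect_equal(sf$sharedLevelCount, 3L)
  levels <- vapply(sf$matches, function(m) m@level, "")
  expect_setequal(unique(levels),
                  c("contraindication", "physiological", "substructure"))
  expect_equal(sum(levels == "substructure"), 14L)
  expect_setequal(vapply(sf$matches[levels == "substructure"],
                         function(m) m@value, ""),
                  substructureClasses())
  ## every match carries its two supporting leaf triples
  for (m in sf$matches) expect_length(m@evidence, 2L)
})

test_that("the fixture assessment is a POTENTIAL_DDI at threshold 1", {
  b <- fixtureBundle()
  a <- assessDDI(b$graph, "C9000001", "C9000002",
                 rulebase = defaultRules())
  expect_identical(verdict(a), "POTENTIAL_DDI")
  expect_length(mechanismMatches(a), 2L)
  expect_equal(sharedLevelCount(a), 3L)
  expect_length(a@proof, 2L)
  expect_true(validObject(a))
})

test_that("without layer-1 facts the verdict is NO_EVIDENCE", {
  b <- fixtureBundle()
  tr <- triples(b$raw)
  keep <- !tr$predicate %in% c("inhibits", "induces", "substrate_of")
  g <- classifyGraph(addTriples(emptyGraph(), tr[keep, , drop = FALSE]),
                     b$schema)
  a <- assessDDI(g, "C9000001", "C9000002", rulebase = defaultRules())
  expect_identical(verdict(a), "NO_EVIDENCE")
  expect_length(mechanismMatches(a), 0L)
  expect_equal(sharedLevelCount(a), 3L)  # features remain, mechanisms gone
})

test_that("a threshold above the shared-level count flips the verdict", {
  b <- fixtureBundle()
  expect_identical(verdict(assessDDI(b$graph, "C9000001", "C9000002",
                                     theta = 3)), "POTENTIAL_DDI")
  expect_identical(verdict(assessDDI(b$graph, "C9000001", "C9000002",
                                     theta = 4)), "NO_EVIDENCE")
})

test_that("assessments are symmetric up to role labeling", {
  b <- fixtureBundle()
  rb <- defaultRules()
  for (seed in c(2, 9, 17)) {
    g <- randomDdiGraph(seed)
    a1 <- assessDDI(g, "C8200001", "C8200002", rulebase = rb)
    a2 <- assessDDI(g, "C8200002", "C8200001", rulebase = rb)
    expect_identical(verdict(a1), verdict(a2))
    expect_identical(mechanismKeys(mechanismMatches(a1)),
                     mechanismKeys(mechanismMatches(a2)))
    fk <- function(a) sort(vapply(featureMatches(a), function(m)
      paste(m@level, m@value, sep = "\r"), ""))
    expect_identical(fk(a1), fk(a2))
  }
  a1 <- assessDDI(b$graph, "C9000001", "C9000002", rulebase = rb)
  a2 <- assessDDI(b$graph, "C9000002", "C9000001", rulebase = rb)
  expect_identical(mechanismKeys(mechanismMatches(a1)),
                   mechanismKeys(mechanismMatches(a2)))
})

test_that("adding feature facts never lowers the shared-level count", {
  rb <- defaultRules()
  for (seed in c(4, 13)) {
    g <- randomDdiGraph(seed)
    n0 <- sharedFeatures(g, "C8200001", "C8200002",
                         rulebase = rb)$sharedLevelCount
    g2 <- addTriple(g, "C8200001", "snp_association", "C8800001")
    g2 <- addTriple(g2, "C8200002", "snp_association", "C8800001")
    n1 <- sharedFeatures(g2, "C8200001", "C8200002",
                         rulebase = rb)$sharedLevelCount
    expect_gte(n1, n0)
    expect_equal(n1, n0 + 1L)  # genetic level was not shared before
  }
})

test_that("rankPairs orders by evidence strength with lexicographic ties", {
  rb <- defaultRules()
  g <- emptyGraph()
  mkpair <- function(g, a, b, t, nLevels) {
    g <- addTriple(g, a, "inhibits", t)
    g <- addTriple(g, b, "substrate_of", t)
    g <- addTriple(g, t, "has_role", "metabolizing_enzyme")
    lvls <- list(c("has_effect", "C8700001"),
                 c("snp_association", "C8800001"),
                 c("has_moa", "C8500001"))
    for (k in seq_len(nLevels)) {
      g <- addTriple(g, a, lvls[[k]][[1L]], lvls[[k]][[2L]])
      g <- addTriple(g, b, lvls[[k]][[1L]], lvls[[k]][[2L]])
    }
    g
  }
  g <- mkpair(g, "C8210001", "C8210002", "C8310001", 3L)
  g <- mkpair(g, "C8210003", "C8210004", "C8310002", 2L)
  g <- mkpair(g, "C8210005", "C8210006", "C8310003", 1L)
  pairs <- data.frame(a = c("C8210005", "C8210001", "C8210003"),
                      b = c("C8210006", "C8210002", "C8210004"))
  ranked <- rankPairs(g, pairs, rulebase = rb)
  expect_identical(vapply(ranked, function(a) a@drugA, ""),
                   c("C8210001", "C8210003", "C8210005"))
  expect_identical(vapply(ranked, sharedLevelCount, 1L), c(3L, 2L, 1L))
  ## singleton in, singleton out
  single <- rankPairs(g, pairs[2, ], rulebase = rb)
  expect_length(single, 1L)
  ## ties: identical evidence -> pair-id order
  g2 <- emptyGraph()
  g2 <- mkpair(g2, "C8220003", "C8220004", "C8320001", 1L)
  g2 <- mkpair(g2, "C8220001", "C8220002", "C8320002", 1L)
  tied <- rankPairs(g2, data.frame(a = c("C8220003", "C8220001"),
                                   b = c("C8220004", "C8220002")),
                    rulebase = rb)
  expect_identical(vapply(tied, function(a) a@drugA, ""),
                   c("C8220001", "C8220003"))
})

test_that("verdicts equal the forward-closure oracle over all pairs", {
  rb <- defaultRules()
  drugs <- sprintf("C82%05d", 1:4)
  for (seed in 1:15) {
    g <- randomDdiGraph(seed, nDrugs = 4L, nTargets = 2L)
    cl <- triples(forwardClosure(g, rb))
    for (i in 1:3) for (j in (i + 1):4) {
      a <- assessDDI(g, drugs[[i]], drugs[[j]], rulebase = rb)
      oracle <- any(cl$predicate == "potential_ddi" &
                      cl$subject == drugs[[i]] & cl$object == drugs[[j]])
      expect_identical(verdict(a) == "POTENTIAL_DDI", oracle,
                       info = sprintf("seed %d %s/%s", seed, drugs[[i]],
                                      drugs[[j]]))
    }
  }
})
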