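test_that("the default schema has the four-class / seven-subclass shape", {
  s <- defaultSchema()
  expect_identical(s@coreClasses,
                   c("pharmacological", "biomolecular", "physiological",
                     "genetic"))
  expect_length(s@subclasses, 7L)
  expect_identical(
    s@subclasses,
    c(drugs = "pharmacological", genes = "biomolecular",
      enzymes = "biomolecular", biological_processes = "biomolecular",
      effect = "physiological", mechanism_of_action = "physiological",
      snps = "genetic"))
  expect_true(all(s@subclasses %in% s@coreClasses))
  expect_identical(unname(s@semtypeMap[["T028"]]), "genes")
  expect_true(validObject(s))
})

test_that("semantic-type overrides apply on top of the defaults", {
  s <- defaultSchema(semtypeMap = c(T999 = "snps", T028 = "enzymes"))
  expect_identical(unname(s@semtypeMap[["T999"]]), "snps")
  expect_identical(unname(s@semtypeMap[["T028"]]), "enzymes")
  expect_error(defaultSchema(semtypeMap = c(T999 = "nonesuch")))
})

test_that("classification follows the semantic-type map", {
  s <- defaultSchema()
  g <- declareEntity(emptyGraph(), "C0000001", semtypes = "T028")
  g <- declareEntity(g, "C0000002", semtypes = character())
  g <- declareEntity(g, "C0000003", semtypes = c("T121", "T086"))
  g <- classifyGraph(g, s)
  e1 <- entities(g)[["C0000001"]]
  expect_identical(e1$subclass, "genes")
  expect_identical(e1$coreClass, "biomolecular")
  e2 <- entities(g)[["C0000002"]]
  expect_true(is.na(e2$subclass) && is.na(e2$coreClass))
  e3 <- entities(g)[["C0000003"]]
  expect_setequal(e3$subclassCandidates, c("drugs", "snps"))
  expect_true(is.na(e3$coreClass))
})

test_that("classification is idempotent and partitions mapped entities", {
  g <- fixtureBundle()$graph
  s <- defaultSchema()
  expect_identical(graphSignature(classifyGraph(g, s)), graphSignature(g))
  ## recount: per-subclass counts sum to the mapped-entity count
  ents <- entities(g)
  mapped <- sum(vapply(ents, function(e) !is.na(e$subclass), TRUE))
  bySub <- table(vapply(ents, function(e) e$subclass, "")[
    vapply(ents, function(e) !is.na(e$subclass), TRUE)])
  expect_equal(sum(bySub), mapped)
  stm <- defaultSchema()@semtypeMap
  brute <- sum(vapply(ents, function(e) {
    cand <- unique(unname(stm[intersect(e$semtypes, names(stm))]))
    length(cand) == 1L
  }, TRUE))
  expect_equal(mapped, brute)
})

test_that("the canonical fixture validates consistent", {
  b <- fixtureBundle()
  rep <- checkConsistency(b$graph, b$schema)
  expect_true(isConsistent(rep))
  expect_equal(nrow(violations(rep)), 0L)
  expect_equal(nrow(rep@warnings), 0L)
})

test_that("an empty graph is consistent", {
  rep <- checkConsistency(emptyGraph(), defaultSchema())
  expect_true(isConsistent(rep))
})

test_that("each planted defect yields exactly one violation of its kind", {
  s <- defaultSchema()
  kinds <- c("MULTI_CLASS_CONFLICT", "UNKNOWN_PREDICATE",
             "DOMAIN_VIOLATION", "RANGE_VIOLATION")
  for (seed in 1:10) {
    g0 <- randomDdiGraph(seed, nDrugs = 4L, nTargets = 2L)
    ## type the random graph so it is defect-free
    for (id in names(entities(g0))) {
      ty <- if (grepl("^C82", id)) "T121" else if (grepl("^C83", id))
        "T126" else if (grepl("^C87", id)) "T046" else "T126"
      g0 <- declareEntity(g0, id, semtypes = ty)
    }
    base <- checkConsistency(classifyGraph(g0, s), s)
    expect_true(isConsistent(base), info = sprintf("seed %d", seed))
    for (kind in kinds) {
      g1 <- classifyGraph(plantDefect(g0, kind), s)
      rep <- checkConsistency(g1, s)
      expect_equal(sum(violations(rep)$kind == kind), 1L,
                   info = sprintf("seed %d kind %s", seed, kind))
      expect_equal(nrow(violations(rep)), 1L,
                   info = sprintf("seed %d kind %s", seed, kind))
    }
  }
})

test_that("unclassified entities warn by default and can be escalated", {
  s <- defaultSchema()
  g <- classifyGraph(declareEntity(emptyGraph(), "C0000001"), s)
  rep <- checkConsistency(g, s)
  expect_true(isConsistent(rep))
  expect_equal(nrow(rep@warnings), 1L)
  strict <- checkConsistency(g, s, strictUnclassified = TRUE)
  expect_false(isConsistent(strict))
  expect_identical(violations(strict)$kind, "UNCLASSIFIED")
})

test_that("domain/range checking can be disabled", {
  s <- defaultSchema()
  g <- classifyGraph(plantDefect(emptyGraph(), "RANGE_VIOLATION"), s)
  expect_false(isConsistent(checkConsistency(g, s)))
  expect_true(isConsistent(checkConsistency(g, s, checkDomainRange = FALSE)))
})

test_that("consistency reports serialize to stable JSON", {
  s <- defaultSchema()
  g <- classifyGraph(plantDefect(emptyGraph(), "DOMAIN_VIOLATION"), s)
  rep <- checkConsistency(g, s)
  j <- jsonlite::fromJSON(consistencyReportJSON(rep),
                          simplifyVector = FALSE)
  expect_false(j$is_consistent)
  expect_length(j$violations, 1L)
  expect_identical(j$violations[[1L]]$kind, "DOMAIN_VIOLATION")
})
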