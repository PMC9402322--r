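test_that("the fixture manifest counts equal an independent line recount", {
  fx <- fixtureBundle()$fx
  m <- fx$manifest
  expect_equal(m$files$mrconso, length(readLines(fx$files[["mrconso"]])))
  expect_equal(m$files$mrrel, length(readLines(fx$files[["mrrel"]])))
  expect_equal(m$files$mrsat, length(readLines(fx$files[["mrsat"]])))
  expect_equal(m$files$links, length(readLines(fx$files[["links"]])) - 1L)
  expect_equal(m$triples_expected, m$files$mrrel + m$files$links)
})

test_that("the fixture encodes fourteen substructure classes", {
  expect_length(substructureClasses(), 14L)
  expect_false(anyDuplicated(substructureClasses()) > 0L)
  lines <- readLines(fixtureBundle()$fx$files[["links"]])
  expect_equal(sum(grepl("has_substructure_class", lines)), 28L)
})

test_that("fixture generation is deterministic", {
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- canonicalFixture(d1); f2 <- canonicalFixture(d2)
  for (k in names(f1$files))
    expect_identical(readLines(f1$files[[k]]), readLines(f2$files[[k]]),
                     info = k)
})

test_that("simulation output is byte-identical for a fixed seed", {
  p <- simParams(seed = 42L)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulateSources(p, d1); s2 <- simulateSources(p, d2)
  for (k in names(s1$files))
    expect_identical(readLines(s1$files[[k]]), readLines(s2$files[[k]]),
                     info = k)
  s3 <- simulateSources(simParams(seed = 43L), tempfile())
  expect_false(identical(readLines(s1$files[["links"]]),
                         readLines(s3$files[["links"]])))
})

test_that("degenerate background leaves exactly the planted DDI", {
  p <- simParams(nDrugs = 6L, nEnzymes = 2L, nTransporters = 1L,
                 pInhibits = 0, pInduces = 0, pSubstrate = 0,
                 pFeature = 0, nPlanted = 1L, seed = 5L)
  res <- simulateSources(p, tempfile())
  b <- buildGraphFromFiles(res$files[["mrconso"]], res$files[["mrrel"]],
                           res$files[["mrsat"]], res$files[["links"]])
  g <- classifyGraph(b$graph, defaultSchema())
  rb <- defaultRules()
  hits <- character()
  drugs <- res$drugs
  for (i in seq_len(length(drugs) - 1L)) {
    for (j in seq(i + 1L, length(drugs))) {
      a <- assessDDI(g, drugs[[i]], drugs[[j]], rulebase = rb)
      if (verdict(a) == "POTENTIAL_DDI")
        hits <- c(hits, paste(drugs[[i]], drugs[[j]]))
    }
  }
  expect_length(hits, 1L)
  pl <- res$truth$planted[[1L]]
  expect_identical(hits, paste(sort(c(pl$drug_a, pl$drug_b)),
                               collapse = " "))
})

test_that("pipeline verdicts equal the generation-time ground truth", {
  rb <- defaultRules()
  for (seed in c(1L, 8L)) {
    p <- simParams(nDrugs = 8L, seed = seed)
    res <- simulateSources(p, tempfile())
    b <- buildGraphFromFiles(res$files[["mrconso"]], res$files[["mrrel"]],
                             res$files[["mrsat"]], res$files[["links"]])
    g <- classifyGraph(b$graph, defaultSchema())
    truthSet <- vapply(
      Filter(function(x) isTRUE(x$potential_ddi), res$truth$pairs),
      function(x) paste(x$drug_a, x$drug_b), "")
    drugs <- res$drugs
    for (i in seq_len(length(drugs) - 1L)) {
      for (j in seq(i + 1L, length(drugs))) {
        a <- assessDDI(g, drugs[[i]], drugs[[j]], rulebase = rb)
        expect_identical(verdict(a) == "POTENTIAL_DDI",
                         paste(drugs[[i]], drugs[[j]]) %in% truthSet,
                         info = sprintf("seed %d %s-%s", seed,
                                        drugs[[i]], drugs[[j]]))
      }
    }
  }
})

test_that("simulated graphs pass the consistency check", {
  s <- defaultSchema()
  for (seed in c(3L, 12L)) {
    res <- simulateSources(simParams(nDrugs = 6L, seed = seed), tempfile())
    b <- buildGraphFromFiles(res$files[["mrconso"]], res$files[["mrrel"]],
                             res$files[["mrsat"]], res$files[["links"]])
    rep <- checkConsistency(classifyGraph(b$graph, s), s)
    expect_true(isConsistent(rep), info = sprintf("seed %d", seed))
  }
})

test_that("infeasible parameters are rejected", {
  expect_error(simParams(nDrugs = 3L, nPlanted = 2L), "disjoint")
  expect_error(simParams(pInhibits = 1.5), "probabilities")
  expect_error(simParams(nEnzymes = 0L, nTransporters = 0L,
                         nPlanted = 1L), "enzyme or transporter")
})
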