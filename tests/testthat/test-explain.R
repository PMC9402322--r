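test_that("a drug's profile lists its mechanistic facts, grouped both ways", {
  b <- fixtureBundle()
  p <- featureProfile(b$graph, "C9000002")  # levofloxacin
  allFacts <- do.call(rbind, unname(p@perSource))
  expect_true(any(allFacts$predicate == "inhibits" &
                    allFacts$value == "C9000003"))
  expect_true(any(allFacts$predicate == "inhibits" &
                    allFacts$value == "C9000004"))
  ## both groupings cover the same fact multiset
  byClass <- do.call(rbind, unname(p@perClass))
  key <- function(df) sort(paste(df$predicate, df$value, df$direction))
  expect_identical(key(allFacts), key(byClass))
})

test_that("profiles equal the pattern-query oracle over registered predicates", {
  b <- fixtureBundle()
  reg <- defaultPredicateRegistry()
  for (drug in c("C9000001", "C9000002")) {
    p <- featureProfile(b$graph, drug)
    got <- do.call(rbind, unname(p@perSource))
    outO <- matchTriples(b$graph, triplePattern(drug, "?p", "?o"))
    inO <- matchTriples(b$graph, triplePattern("?s", "?p", drug))
    oracle <- sort(c(
      paste(outO$p[outO$p %in% reg$predicate],
            outO$o[outO$p %in% reg$predicate]),
      paste(inO$p[inO$p %in% reg$predicate],
            inO$s[inO$p %in% reg$predicate])))
    expect_identical(sort(paste(got$predicate, got$value)), oracle)
  }
})

test_that("a drug with no facts has an empty profile", {
  g <- declareEntity(emptyGraph(), "C0000001", labels = "inert")
  p <- featureProfile(g, "C0000001")
  expect_length(p@perSource, 0L)
  expect_length(p@perClass, 0L)
  expect_error(featureProfile(g, "C0000002"), "C0000002")
})

fixtureAssessment <- function() {
  b <- fixtureBundle()
  assessDDI(b$graph, "C9000001", "C9000002", rulebase = defaultRules())
}

test_that("the markdown report renders the summary-table layout", {
  b <- fixtureBundle()
  a <- fixtureAssessment()
  md <- renderReport(a, "markdown", graph = b$graph)
  expect_match(md, "POTENTIAL_DDI")
  ## the enzyme row shows substrate for irinotecan, inhibitor for
  ## levofloxacin
  enz <- grep("Metabolizing enzymes", strsplit(md, "\n")[[1L]],
              value = TRUE)
  cells <- strsplit(enz, "|", fixed = TRUE)[[1L]]
  expect_match(cells[[3L]], "CYP3A4 substrate")
  expect_match(cells[[4L]], "CYP3A4 inhibitor")
  tra <- grep("^\\| Transporters", strsplit(md, "\n")[[1L]], value = TRUE)
  expect_match(tra, "ABCB1 substrate")
  expect_match(tra, "ABCB1 inhibitor")
  ## empty feature rows render NA
  expect_match(md, "\\| Biomolecular \\| NA \\| NA \\|")
  expect_match(md, "\\| Genetic \\| NA \\| NA \\|")
})

test_that("a NO_EVIDENCE report has an empty mechanism block and a verdict", {
  g <- addTriple(emptyGraph(), "C0000001", "has_effect", "C0000009")
  g <- addTriple(g, "C0000002", "has_effect", "C0000009")
  a <- assessDDI(g, "C0000001", "C0000002", rulebase = defaultRules())
  expect_identical(verdict(a), "NO_EVIDENCE")
  md <- renderReport(a, "markdown")
  expect_match(md, "NO_EVIDENCE")
  expect_match(md, "\\| Metabolizing enzymes \\| NA \\| NA \\|")
  j <- jsonlite::fromJSON(renderReport(a, "json"), simplifyVector = FALSE)
  expect_length(j$pharmacological_effects$metabolizing_enzymes, 0L)
  expect_identical(j$verdict, "NO_EVIDENCE")
})

test_that("the JSON report round-trips all counts and validates", {
  a <- fixtureAssessment()
  txt <- renderReport(a, "json")
  expect_true(validateReportJSON(txt))
  j <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(j$drug_a, a@drugA)
  expect_identical(j$drug_b, a@drugB)
  expect_equal(j$shared_level_count, sharedLevelCount(a))
  expect_equal(j$mechanism_match_count, length(mechanismMatches(a)))
  nm <- length(j$pharmacological_effects$metabolizing_enzymes) +
    length(j$pharmacological_effects$transporters)
  expect_equal(nm, length(mechanismMatches(a)))
  expect_length(j$biomedical_features$substructure, 14L)
  expect_identical(j$biomedical_features$biomolecular, "NA")
})

test_that("reports are pure functions of the assessment", {
  a <- fixtureAssessment()
  expect_identical(renderReport(a, "json"), renderReport(a, "json"))
  expect_identical(renderReport(a, "markdown"), renderReport(a, "markdown"))
  expect_error(renderReport(a, "html"))
})
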