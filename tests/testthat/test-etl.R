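writeTmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("RRF reading skips and counts malformed lines", {
  f <- writeTmp(c("C0000001|NCI|X1|aspirin",
                  "garbage line without pipes",
                  "C0000002|GO|X2|apoptosis"))
  r <- readRRF(f, "MRCONSO")
  expect_equal(r$parsed, 2L)
  expect_equal(r$skipped, 1L)
  expect_equal(r$skippedLines, 2L)
  expect_identical(r$records$label, c("aspirin", "apoptosis"))
})

test_that("empty RRF files yield empty record sets with zero skips", {
  f <- writeTmp(character())
  r <- readRRF(f, "MRSAT")
  expect_equal(nrow(r$records), 0L)
  expect_equal(r$skipped, 0L)
})

test_that("a file of the wrong dialect is a hard error, as is a missing file", {
  conso <- writeTmp(c("C0000001|NCI|X1|aspirin"))
  expect_error(readRRF(conso, "MRREL"), "wrong kind")
  expect_error(readRRF(tempfile(), "MRCONSO"), "not found")
  csv <- writeTmp(c("a,b", "1,2"))
  expect_error(readLinkCSV(csv), "header")
})

test_that("a PharmGKB-style link with a CUI lands under that CUI", {
  f <- writeTmp(c("external_id,external_source,cui,relation,target",
                  "PA450214,PHARMGKB_LIKE,C0000002,gene_association,C0000008"))
  li <- readLinkCSV(f)
  out <- buildGraph(links = li$records)
  tr <- triples(out$graph)
  expect_equal(nrow(tr), 1L)
  expect_identical(tr$subject, "C0000002")
  expect_identical(tr$predicate, "gene_association")
  expect_identical(tr$object, "C0000008")
  expect_identical(tr$provenance, "GENELINK")
})

test_that("external ids without a CUI resolve through aliases or fall back prefixed", {
  f <- writeTmp(c("external_id,external_source,cui,relation,target",
                  "DB00001,DRUGBANK_LIKE,C0000001,inhibits,C0000003",
                  "DB00001,DRUGBANK_LIKE,,substrate_of,C0000004",
                  "DB09999,DRUGBANK_LIKE,,inhibits,C0000005"))
  out <- buildGraph(links = readLinkCSV(f)$records)
  tr <- triples(out$graph)
  ## aliased record joins under the CUI; orphan keeps a prefixed id
  expect_true(any(tr$subject == "C0000001" & tr$predicate == "substrate_of"))
  expect_true(any(tr$subject == "DB:DB09999" & tr$predicate == "inhibits"))
  expect_identical(out$report@unresolvedLinks, "DB09999")
})

test_that("zero input records give an empty graph and empty report", {
  out <- buildGraph()
  expect_equal(nTriples(out$graph), 0L)
  expect_equal(nrow(out$report@perSource), 0L)
})

test_that("MRREL predicates come from RELA, else the normalized REL", {
  f <- writeTmp(c("C0000001|RO|inhibits|C0000003|NCI",
                  "C0000001|PAR||C0000002|NCI",
                  "C0000001|RB||C0000004|NCI",
                  "C0000001|RO||C0000005|NCI"))
  out <- buildGraph(relations = readRRF(f, "MRREL")$records)
  tr <- triples(out$graph)
  expect_setequal(tr$predicate, c("inhibits", "parent_of", "broader",
                                  "related_to"))
})

test_that("MRSAT SEMTYPE rows become semantic types, others become triples", {
  f <- writeTmp(c("C0000001|SEMTYPE|t121",
                  "C0000001|DOSE_FORM|tablet"))
  out <- buildGraph(attributes = readRRF(f, "MRSAT")$records)
  e <- entities(out$graph)[["C0000001"]]
  expect_identical(e$semtypes, "T121")
  tr <- triples(out$graph)
  expect_identical(tr$predicate, "dose_form")
  expect_true(tr$literal)
})

test_that("per-source triple counts recount to the graph size", {
  b <- fixtureBundle()
  ps <- b$report@perSource
  expect_equal(sum(ps$triples), nTriples(b$raw))
  ## and per provenance tag
  tr <- triples(b$raw)
  for (i in seq_len(nrow(ps))) {
    if (ps$source[[i]] %in% tr$provenance)
      expect_equal(ps$triples[[i]], sum(tr$provenance == ps$source[[i]]))
  }
  expect_equal(sum(ps$skipped), 0L)
})

test_that("no record is lost without trace on randomized inputs", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:12, 1L)
    good <- sprintf("C%07d|RO|inhibits|C%07d|NCI",
                    sample(1:50, n, replace = TRUE),
                    sample(51:99, n, replace = TRUE))
    nbad <- sample(0:3, 1L)
    bad <- rep("BADLINE", nbad)
    f <- writeTmp(sample(c(good, bad)))
    r <- readRRF(f, "MRREL")
    expect_equal(r$parsed + r$skipped, n + nbad)
    out <- buildGraph(relations = r$records)
    expect_equal(nTriples(out$graph), nrow(unique(r$records)))
  }
})

test_that("graph building is deterministic", {
  b <- fixtureBundle()
  again <- buildGraphFromFiles(b$fx$files[["mrconso"]],
                               b$fx$files[["mrrel"]],
                               b$fx$files[["mrsat"]],
                               b$fx$files[["links"]])
  expect_identical(graphSignature(again$graph), graphSignature(b$raw))
  expect_identical(loadReportJSON(again$report), loadReportJSON(b$report))
})
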