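# Readers/writers for GMT gene sets, JSONL corpora, edge lists and labeled
# TSV matrices, plus identifier normalization.

test_that("GMT reading normalizes, deduplicates and validates", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tp1\tP2\tp2", "T2\tdesc\ta\tb\tc"), gmt)
  gs <- readGeneSets(gmt)
  expect_setequal(geneSets(gs)$T1, c("P1", "P2"))
  expect_equal(lengths(geneSets(gs))[["T2"]], 3L)

  empty <- withr::local_tempfile(fileext = ".gmt")
  file.create(empty)
  expect_length(geneSets(readGeneSets(empty)), 0L)

  writeLines(c("T1\tdesc\ta\tb\tc", "T2\tdesc\ta\tb\tc\td\te"), gmt)
  expect_equal(unname(lengths(geneSets(readGeneSets(gmt)))), c(3L, 5L))

  writeLines("onlyonefield", gmt)
  expect_error(readGeneSets(gmt), "line 1")
  writeLines(c("T1\td\ta", "T1\td\tb"), gmt)
  expect_error(readGeneSets(gmt), "duplicate set name")
})

test_that("corpus JSONL reading preserves order, dedupes and normalizes", {
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"id":"a1","entities":{"proteins":["AKT1","akt1"]}}',
    '{"id":"a2","entities":{"microRNAs":["miR-146a-5p","hsa-miR-21"]}}',
    '{"id":"a3","entities":{}}'
  ), jl)
  cp <- readCorpus(jl)
  expect_equal(abstractIds(cp), c("a1", "a2", "a3"))
  expect_length(cp, 3L)
  expect_equal(mentions(cp)[["a1"]]$proteins, "AKT1")
  expect_setequal(mentions(cp)[["a2"]]$microRNAs, c("mir-146a-5p", "mir-21"))

  writeLines(c('{"id":"a1"}', '{"id":"a1"}'), jl)
  expect_error(readCorpus(jl), "duplicate abstract id")
  writeLines('{"entities":{}}', jl)
  expect_error(readCorpus(jl), "record 1")
})

test_that("microRNA normalization is canonical and idempotent", {
  x <- c("miR-155", "hsa-miR-34a", "let-7a", "mir-146a", "mir-146a-5p")
  once <- normalizeMirna(x)
  expect_equal(once, c("mir-155", "mir-34a", "mir-let-7a", "mir-146a",
                       "mir-146a-5p"))
  expect_equal(normalizeMirna(once), once)
  # no arm inference: armless and armed forms are distinct
  expect_length(unique(normalizeMirna(c("mir-146a", "mir-146a-5p"))), 2L)
})

test_that("edge lists canonicalize, drop self-loops and ignore line order", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB", "B\tA", "C\tC"), tsv)
  g <- suppressMessages(readEdgeList(tsv))
  expect_equal(nrow(g@edges), 1L)
  expect_setequal(g@nodes, c("A", "B", "C"))

  file.create(tsv)
  writeLines(character(), tsv)
  g0 <- readEdgeList(tsv)
  expect_length(g0@nodes, 0L)
  expect_equal(nrow(g0@edges), 0L)

  lines <- c("P1\tP2", "P2\tP3", "P3\tP4", "P4\tP5")
  writeLines(lines, tsv)
  g1 <- readEdgeList(tsv)
  set.seed(4)
  writeLines(sample(lines), tsv)
  g2 <- readEdgeList(tsv)
  expect_equal(nrow(g1@edges), 4L)
  expect_length(g1@nodes, 5L)
  expect_setequal(apply(g1@edges, 1, paste, collapse = "-"),
                  apply(g2@edges, 1, paste, collapse = "-"))

  writeLines("A\tB\tC", tsv)
  expect_error(readEdgeList(tsv), "2 columns")
})

test_that("labeled matrix TSVs round-trip integer matrices losslessly", {
  m <- matrix(c(0L, 7L, 3L, 12L), 2, 2,
              dimnames = list(c("S1", "S2"), c("D1", "D2")))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeMatrixTsv(m, p)
  expect_length(readLines(p), 3L)
  back <- readMatrixTsv(p)
  expect_identical(back, matrix(as.numeric(m), 2, 2, dimnames = dimnames(m)))
  expect_equal(back["S1", "D2"], 3)

  m0 <- matrix(numeric(), 0, 0)
  writeMatrixTsv(m0, p)
  expect_length(readLines(p), 1L)

  bad <- matrix(1:4, 2, 2, dimnames = list(c("a", "a"), c("x", "y")))
  expect_error(writeMatrixTsv(bad, p), "duplicate")
})

test_that("unresolvable mentions are dropped with a warning, not an error", {
  voc <- entityVocabulary(proteins = c("AKT1", "TP53"),
                          diseases = "covid-19", microRNAs = "mir-21")
  cp <- corpus("a1", list(list(proteins = c("AKT1", "UNKNOWN1"),
                               diseases = c("covid-19", "nosuch"))))
  expect_warning(out <- resolveMentions(cp, voc), "2 unresolvable")
  expect_equal(mentions(out)[["a1"]]$proteins, "AKT1")
  expect_equal(mentions(out)[["a1"]]$diseases, "covid-19")
})

test_that("vocabulary classes must be disjoint and non-empty", {
  expect_error(entityVocabulary(proteins = "AKT1", diseases = "AKT1"),
               "disjoint")
  expect_error(entityVocabulary(proteins = c("A", "")), "empty identifier")
})
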