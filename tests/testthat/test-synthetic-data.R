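# Planted-block generators: determinism, feasibility checks, signal
# contract, and round-trips through the file formats.

test_that("generators are pure functions of the config seed", {
  cfg <- tinyConfig(seed = 1L)
  u1 <- makeUniverse(cfg)
  u2 <- makeUniverse(cfg)
  expect_identical(geneSets(u1$tissues), geneSets(u2$tissues))
  expect_identical(u1$truth@block_of_swarm, u2$truth@block_of_swarm)
  c1 <- makeCorpus(u1, cfg)
  c2 <- makeCorpus(u2, cfg)
  expect_identical(mentions(c1$corpus), mentions(c2$corpus))
  g1 <- makeInteractions(u1, cfg)
  g2 <- makeInteractions(u2, cfg)
  expect_identical(g1@edges, g2@edges)
})

test_that("universe geometry matches the planted design", {
  cfg <- syntheticConfig(n_proteins = 60L, n_tissues = 1L, n_processes = 2L,
                         n_blocks = 1L, n_mirnas = 4L, n_diseases = 6L,
                         module_size = 10L, seed = 2L)
  u <- makeUniverse(cfg)
  expect_length(unique(u$truth@block_of_swarm), 1L)
  # at most n_tissues * n_processes overlap modules
  expect_lte(nrow(u$modules), cfg$n_tissues * cfg$n_processes)
  # tissue x process intersections equal the planted modules exactly
  for (m in seq_len(nrow(u$modules))) {
    inter <- intersect(geneSets(u$tissues)[[u$modules$tissue[m]]],
                       geneSets(u$processes)[[u$modules$process_name[m]]])
    expect_setequal(inter, u$modules$members[[m]])
  }
  expect_error(
    syntheticConfig(n_proteins = 10L, n_blocks = 2L, n_tissues = 2L,
                    n_processes = 2L, module_size = 10L),
    "cannot place"
  )
  expect_error(syntheticConfig(p_in = 0.1, p_out = 0.2), "exceed")
})

test_that("p_out = 0 forces zero background co-citation", {
  cfg <- syntheticConfig(n_proteins = 100L, n_tissues = 2L, n_processes = 2L,
                         n_blocks = 2L, n_diseases = 8L, n_functions = 4L,
                         n_mirnas = 4L, module_size = 5L, p_in = 0.8,
                         p_out = 0, n_abstracts = 150L, seed = 5L)
  u <- makeUniverse(cfg)
  cc <- makeCorpus(u, cfg)
  truth <- u$truth
  # a block-1 protein never co-occurs with a block-2 disease
  p1 <- u$modules$members[[which(u$modules$block == 1L)[1]]][1]
  d2 <- names(truth@block_of_concept)[truth@block_of_concept == "block02"][1]
  cnt <- cocitationCount(cc$corpus, p1, d2)
  expect_identical(cnt, 0L)
  # empty corpus
  cfg0 <- syntheticConfig(n_abstracts = 0L, n_proteins = 100L,
                          n_tissues = 1L, n_processes = 1L, n_blocks = 1L,
                          module_size = 5L, n_diseases = 2L, n_mirnas = 1L)
  expect_length(makeCorpus(makeUniverse(cfg0), cfg0)$corpus, 0L)
})

test_that("within-block co-citation exceeds background in every block", {
  # 6 blocks x 20 swarm proteins, 40 disease concepts, 2000 abstracts
  cfg <- syntheticConfig(n_proteins = 800L, n_tissues = 6L, n_processes = 2L,
                         n_blocks = 6L, n_diseases = 40L, n_functions = 6L,
                         n_mirnas = 6L, module_size = 10L, p_in = 0.6,
                         p_out = 0.02, n_abstracts = 2000L, filler = 5L,
                         seed = 7L)
  u <- makeUniverse(cfg)
  cc <- makeCorpus(u, cfg)
  cat <- buildSwarmCatalog(u$tissues, u$processes, u$vocabulary@proteins)
  spec <- buildSpectrumMatrix(cc$corpus, cat, u$vocabulary@diseases)
  truth <- u$truth
  m <- counts(spec)
  sb <- truth@block_of_swarm[rownames(m)]
  cb <- truth@block_of_concept[colnames(m)]
  for (b in unique(sb)) {
    inside <- mean(m[sb == b, cb == b])
    outside <- mean(m[sb == b, cb != b])
    expect_gt(inside, outside)
  }
})

test_that("planted interaction graphs obey the module structure", {
  cfg <- syntheticConfig(n_proteins = 50L, n_tissues = 2L, n_processes = 1L,
                         n_blocks = 2L, module_size = 5L, n_diseases = 2L,
                         n_mirnas = 2L, seed = 11L)
  u <- makeUniverse(cfg)
  # q_in = 1, q_out = 0: two complete modules, no cross edges
  g <- makeInteractions(u, cfg, q_in = 1, q_out = 0)
  expect_equal(nrow(g@edges), 2 * choose(5, 2))
  st <- inducedSubgraphStats(g, unlist(u$modules$members))
  expect_equal(st$n_components, 2L)
})

test_that("generated corpora survive the JSONL round-trip", {
  cfg <- tinyConfig(seed = 9L)
  u <- makeUniverse(cfg)
  cc <- makeCorpus(u, cfg)
  p <- withr::local_tempfile(fileext = ".jsonl")
  writeCorpus(cc$corpus, p)
  back <- readCorpus(p)
  expect_identical(abstractIds(back), abstractIds(cc$corpus))
  expect_identical(mentions(back), mentions(cc$corpus))
})
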