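# PSA extraction, microRNA clustering, PSA-microRNA linkage and the
# end-to-end pipeline bundle.

.tinyCatalog <- function() {
  new("SwarmCatalog",
    swarm_id = c("s1", "s2", "s3"),
    tissue = rep("t", 3), process = rep("p", 3),
    members = list(c("A", "B"), c("B", "C"), c("D", "E"))
  )
}

test_that("extractPsas unions member proteins in leaf order", {
  part <- new("ClusterPartition", threshold = 0.5,
              clusters = list(C1 = c("s1", "s2"), C2 = "s3"),
              ccsv = c(C1 = 0.9, C2 = 1))
  psas <- extractPsas(part, .tinyCatalog())
  expect_equal(psas$psa_id, c("PSA1", "PSA2"))
  expect_setequal(psas$proteins[[1]], c("A", "B", "C"))
  expect_equal(psas$n_proteins, c(3L, 2L))
  expect_equal(psas$ccsv, c(0.9, 1))

  bad <- new("ClusterPartition", threshold = 0.5,
             clusters = list(C1 = "nope"), ccsv = c(C1 = 1))
  expect_error(extractPsas(bad, .tinyCatalog()), "unknown swarm")

  # PSA protein unions conserve the clustered proteins
  expect_setequal(unique(unlist(psas$proteins)),
                  unique(unlist(swarmMembers(.tinyCatalog()))))
})

test_that("clusterMirnas groups identical profiles and splits orthogonal ones", {
  m <- matrix(c(5L, 5L, 0L,
                9L, 9L, 0L,
                0L, 0L, 7L,
                1L, 1L, 8L), 4, 3, byrow = TRUE,
              dimnames = list(sprintf("s%d", 1:4),
                              c("mir-1", "mir-2", "mir-3")))
  sp <- new("SpectrumMatrix", counts = m, corpus_size = 20L,
            mode = "any-member")
  cm <- clusterMirnas(sp, threshold = 0.67)
  cl <- clusterMembers(cm$partition)
  expect_true(any(vapply(cl, function(x) setequal(x, c("mir-1", "mir-2")),
                         TRUE)))
  expect_true(any(vapply(cl, function(x) identical(sort(x), "mir-3"), TRUE)))
  expect_equal(cm$clusters$cluster_id, LETTERS[seq_len(nrow(cm$clusters))])
  expect_error(clusterMirnas(sp@counts[, 1, drop = FALSE]), "at least 2")
})

test_that("mapMirnaClusters links exactly the planted block", {
  m <- matrix(0L, 4, 4, dimnames = list(sprintf("s%d", 1:4),
                                        sprintf("mir-%d", 1:4)))
  m[1:2, 1:2] <- 9L
  sp <- new("SpectrumMatrix", counts = m, corpus_size = 50L,
            mode = "any-member")
  psas <- data.frame(psa_id = c("PSA1", "PSA2"), n_swarms = 2L,
                     n_proteins = 2L, ccsv = 1)
  psas$swarms <- list(c("s1", "s2"), c("s3", "s4"))
  psas$proteins <- list(c("A", "B"), c("C", "D"))
  mcs <- data.frame(cluster_id = c("A", "B"), n_members = 2L, ccsv = 1)
  mcs$members <- list(c("mir-1", "mir-2"), c("mir-3", "mir-4"))

  am <- mapMirnaClusters(sp, psas, mcs, factor = 2)
  expect_equal(nrow(am), 4L)
  linked <- am[am$linked, ]
  expect_equal(nrow(linked), 1L)
  expect_equal(linked$psa_id, "PSA1")
  expect_equal(linked$mirna_cluster, "A")
  expect_equal(linked$background_mean, 0)
  expect_equal(linked$enrichment_ratio, Inf)

  # all-zero spectrum: nothing links
  sp0 <- new("SpectrumMatrix", counts = m * 0L, corpus_size = 50L,
             mode = "any-member")
  expect_false(any(mapMirnaClusters(sp0, psas, mcs)$linked))
})

test_that("linkage is invariant to microRNA column permutation", {
  cfg <- tinyConfig(seed = 13L)
  res <- runPipeline(pipelineConfig(simulate = cfg, seed = 13L))
  sp <- res$mirna_spectrum
  perm <- sample(ncol(counts(sp)))
  sp2 <- new("SpectrumMatrix", counts = counts(sp)[, perm],
             corpus_size = corpusSize(sp), mode = countingMode(sp))
  mir2 <- clusterMirnas(sp2, threshold = 0.67)
  am1 <- res$association_map
  am2 <- mapMirnaClusters(sp2, res$psas, mir2$clusters)
  key <- function(am, mir_members) {
    lk <- am[am$linked, ]
    sort(paste(lk$psa_id,
               vapply(mir_members[lk$mirna_cluster],
                      function(x) paste(sort(x), collapse = ","), "")))
  }
  mm1 <- setNames(res$mirna_clusters$members, res$mirna_clusters$cluster_id)
  mm2 <- setNames(mir2$clusters$members, mir2$clusters$cluster_id)
  expect_identical(key(am1, mm1), key(am2, mm2))
})

test_that("the pipeline bundle is consistent and deterministic", {
  cfg <- tinyConfig(seed = 21L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- runPipeline(pipelineConfig(simulate = cfg, seed = 21L), d1)
  r2 <- runPipeline(pipelineConfig(simulate = cfg, seed = 21L), d2)
  expect_identical(r1$manifest, r2$manifest)
  expect_identical(readLines(file.path(d1, "manifest.json")),
                   readLines(file.path(d2, "manifest.json")))

  # PSA protein-union conservation over the whole catalog
  expect_setequal(unique(unlist(r1$psas$proteins)),
                  unique(unlist(swarmMembers(r1$catalog))))

  # recovery on the planted truth
  rec <- evaluateRecovery(r1)
  expect_gte(rec$swarm_ari, 0.9)
  expect_gte(rec$mirna_ari, 0.9)

  # infeasible rates are refused before any work
  expect_error(pipelineConfig(simulate = list(p_in = 0.1, p_out = 0.4)),
               "exceed")
  expect_error(runPipeline(pipelineConfig(tissues = "no.gmt",
                                          processes = "no.gmt",
                                          corpus = "no.jsonl")),
               "missing input")
})

test_that("file-based and simulate-based runs agree on the same inputs", {
  cfg <- tinyConfig(seed = 5L)
  dir <- withr::local_tempdir()
  sim <- simulateStudy(cfg, dir)
  res_f <- runPipeline(pipelineConfig(
    tissues = file.path(dir, "tissues.gmt"),
    processes = file.path(dir, "processes.gmt"),
    corpus = file.path(dir, "corpus.jsonl"),
    interactions = file.path(dir, "interactions.tsv"),
    universe = file.path(dir, "universe.txt"),
    seed = 5L
  ))
  res_s <- runPipeline(pipelineConfig(simulate = cfg, seed = 5L))
  expect_identical(swarmIds(res_f$catalog), swarmIds(res_s$catalog))
  expect_identical(counts(res_f$mirna_spectrum), counts(res_s$mirna_spectrum))
  expect_identical(res_f$association_map$linked, res_s$association_map$linked)
})
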