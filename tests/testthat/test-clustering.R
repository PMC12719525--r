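# Similarity matrices, agglomerative merge trees, CCSV cuts, two-way
# clustering and the adjusted Rand index.

test_that("similarityMatrix matches the correlation definition", {
  m <- matrix(c(1, 2, 3, 3, 2, 1, 2, 4, 6), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  s <- similarityMatrix(m, "pearson")$values
  expect_equal(unname(s["a", "c"]), 1)        # identical up to scale
  expect_equal(unname(s["a", "b"]), -1)       # exact anticorrelation
  expect_equal(diag(s), setNames(rep(1, 3), c("a", "b", "c")))
  expect_true(isSymmetric(s))

  set.seed(10)
  r <- matrix(sample.int(20, 24, replace = TRUE), 6, 4,
              dimnames = list(sprintf("g%d", 1:6), NULL))
  expect_equal(similarityMatrix(r, "pearson")$values,
               cor(t(r)), tolerance = 1e-12)
  expect_equal(similarityMatrix(r, "spearman")$values,
               cor(t(r), method = "spearman"), tolerance = 1e-12)

  const <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))
  expect_error(similarityMatrix(const, "pearson"), "g1")
  bad <- rbind(g1 = c(1, NA, 1), g2 = c(1, 2, 3))
  expect_error(similarityMatrix(bad), "non-finite")
})

test_that("small merge trees follow the forced merge order", {
  s2 <- matrix(c(1, 0.95, 0.95, 1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- hierarchicalMergeTree(s2)
  expect_equal(mergeSimilarity(t2), 0.95)

  s3 <- matrix(0.1, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  s3["A", "B"] <- s3["B", "A"] <- 0.9
  diag(s3) <- 1
  t3 <- hierarchicalMergeTree(s3, "average")
  expect_equal(t3@merge[1, ], c(-2L, -1L))    # (A, B) first
  expect_equal(mergeSimilarity(t3), c(0.9, 0.1), tolerance = 1e-12)
})

test_that("merge trees equal the O(n^3) reference on random inputs", {
  for (seed in 1:20) {
    n <- sample(3:12, 1)
    s <- randomSimilarity(n, seed)
    for (lk in c("average", "complete", "single")) {
      got <- hierarchicalMergeTree(s, lk)
      ref <- refMergeTree(s, lk)
      expect_identical(got@merge, ref$merge)
      expect_equal(got@height, ref$height, tolerance = 1e-9)
    }
  }
})

test_that("merge trees agree with stats::hclust on tie-free inputs", {
  set.seed(77)
  for (lk in c("average", "complete", "single")) {
    s <- randomSimilarity(9, 1234)
    got <- hierarchicalMergeTree(s, lk)
    ref <- stats::hclust(stats::as.dist(1 - s), method = lk)
    expect_equal(sort(got@height), sort(ref$height), tolerance = 1e-12)
  }
})

test_that("ccsvCut keeps subtrees above the threshold", {
  s2 <- matrix(c(1, 0.95, 0.95, 1), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- hierarchicalMergeTree(s2)
  p1 <- ccsvCut(t2, 0.92)
  expect_length(clusterMembers(p1), 1L)
  expect_equal(unname(clusterCcsv(p1)), 0.95)
  p2 <- ccsvCut(t2, 0.973)
  expect_length(clusterMembers(p2), 2L)
  expect_equal(unname(clusterCcsv(p2)), c(1, 1))

  s <- randomSimilarity(8, 3)
  s[s < 0] <- abs(s[s < 0])   # keep all merge similarities positive
  diag(s) <- 1
  tr <- hierarchicalMergeTree(s)
  expect_length(clusterMembers(ccsvCut(tr, 0)), 1L)
})

test_that("cuts refine monotonically in the threshold", {
  for (seed in 1:10) {
    tr <- hierarchicalMergeTree(randomSimilarity(12, seed + 40))
    thresholds <- sort(runif(6, -1, 1), decreasing = TRUE)
    parts <- lapply(thresholds, function(t) ccsvCut(tr, t))
    sizes <- vapply(parts, function(p) length(clusterMembers(p)), 0L)
    expect_true(all(diff(sizes) <= 0))   # fewer clusters at lower cuts
    for (i in seq_len(length(parts) - 1L)) {
      hi <- membership(parts[[i]])
      lo <- membership(parts[[i + 1]])[names(hi)]
      # each high-threshold cluster sits inside one low-threshold cluster
      expect_true(all(tapply(lo, hi, function(x) length(unique(x))) == 1L))
    }
    # beyond the extreme merge similarities the cuts are forced
    expect_length(clusterMembers(ccsvCut(tr, max(tr@similarity) + 1e-9)), 12L)
    expect_length(clusterMembers(ccsvCut(tr, min(tr@similarity) - 1e-9)), 1L)
  }
})

test_that("clustering is invariant to row permutation of the input", {
  set.seed(99)
  m <- matrix(rpois(10 * 6, 4), 10, 6,
              dimnames = list(sprintf("r%02d", 1:10), sprintf("c%d", 1:6)))
  t1 <- hierarchicalMergeTree(similarityMatrix(m))
  perm <- sample(nrow(m))
  t2 <- hierarchicalMergeTree(similarityMatrix(m[perm, ]))
  p1 <- ccsvCut(t1, 0.3)
  p2 <- ccsvCut(t2, 0.3)
  norm <- function(p) {
    cl <- lapply(clusterMembers(p), sort)
    unname(cl[order(vapply(cl, `[[`, "", 1L))])
  }
  expect_identical(norm(p1), norm(p2))
})

test_that("two-way clustering recovers planted blocks and is symmetric", {
  m <- matrix(0L, 4, 4, dimnames = list(sprintf("r%d", 1:4),
                                        sprintf("c%d", 1:4)))
  m[1:2, 1:2] <- 9L
  m[3:4, 3:4] <- 9L
  tw <- twoWayCluster(m)
  rp <- ccsvCut(tw$row_tree, 0.9)
  cp <- ccsvCut(tw$col_tree, 0.9)
  norm <- function(p) {
    cl <- lapply(clusterMembers(p), sort)
    unname(cl[order(vapply(cl, `[[`, "", 1L))])
  }
  expect_identical(norm(rp), list(c("r1", "r2"), c("r3", "r4")))
  expect_identical(norm(cp), list(c("c1", "c2"), c("c3", "c4")))

  # transposing swaps the row/col outputs exactly
  tw_t <- twoWayCluster(t(m))
  expect_identical(tw_t$row_order, tw$col_order)
  expect_identical(tw_t$col_order, tw$row_order)

  m2 <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  tw2 <- twoWayCluster(m2)
  expect_length(mergeSimilarity(tw2$row_tree), 1L)
})

test_that("adjustedRand matches the pair-counting formula", {
  expect_equal(adjustedRand(c(a = 1, b = 1, c = 2), c(a = 1, b = 1, c = 2)), 1)
  expect_equal(adjustedRand(c(a = 1, b = 1, c = 1), c(a = 2, b = 2, c = 2)), 1)
  # {AB|CD} vs {AC|BD}: all pair counts disagree maximally
  a <- c(A = 1, B = 1, C = 2, D = 2)
  b <- c(A = 1, B = 2, C = 1, D = 2)
  expect_equal(adjustedRand(a, b), -0.5)
  expect_error(adjustedRand(a, c(X = 1, Y = 2)), "label universes")

  skip_if_not_installed("mclust")
  set.seed(21)
  for (i in 1:10) {
    x <- setNames(sample.int(4, 12, replace = TRUE), letters[1:12])
    y <- setNames(sample.int(3, 12, replace = TRUE), letters[1:12])
    expect_equal(adjustedRand(x, y),
                 mclust::adjustedRandIndex(x, y[names(x)]),
                 tolerance = 1e-12)
  }
})
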