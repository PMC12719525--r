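# Independent reference implementations used as oracles. These deliberately
# use the slowest, most literal formulation of each quantity and share no
# code with the package.

# P(X >= k) by exhaustive enumeration of all C(N, n) draws of n proteins
# from a universe of N containing K annotated (annotated = 1..K).
refHypergeomTail <- function(k, K, n, N) {
  if (k == 0) return(1)
  if (n == 0) return(if (k == 0) 1 else 0)
  draws <- utils::combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# Benjamini-Hochberg step-up with an explicit running minimum from the
# largest rank down.
refBH <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- 1
  for (r in m:1) {
    idx <- ord[r]
    running <- min(running, p[idx] * m / r)
    q[idx] <- running
  }
  q
}

# brute-force co-citation counts: literal double loop over (row, concept)
# pairs, scanning every abstract's pooled mention set.
bruteSpectrum <- function(corp, members, concepts, mode = "any-member") {
  mention_sets <- lapply(mentions(corp), unlist, use.names = FALSE)
  out <- matrix(0L, length(members), length(concepts),
                dimnames = list(names(members), concepts))
  for (i in seq_along(members)) {
    for (j in seq_along(concepts)) {
      cnt <- 0L
      for (m in mention_sets) {
        if (!(concepts[[j]] %in% m)) next
        hit <- if (mode == "any-member") {
          any(members[[i]] %in% m)
        } else {
          all(members[[i]] %in% m)
        }
        if (hit) cnt <- cnt + 1L
      }
      out[i, j] <- cnt
    }
  }
  out
}

# O(n^3) reference agglomerative clustering: linkage distances are
# recomputed from the original leaf distance matrix at every step (no
# Lance-Williams updates); same tie rule as the package (lexicographically
# smallest pair of cluster representatives, tolerance 1e-9).
refMergeTree <- function(S, linkage) {
  D0 <- 1 - S
  labels <- rownames(S)
  n <- nrow(S)
  clusters <- lapply(seq_len(n), identity)   # leaf index sets
  nodes <- -seq_len(n)
  reps <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  linkfun <- switch(linkage,
    average = function(a, b) mean(D0[a, b]),
    complete = function(a, b) max(D0[a, b]),
    single = function(a, b) min(D0[a, b])
  )
  for (step in seq_len(n - 1L)) {
    k <- length(clusters)
    pairs <- t(utils::combn(k, 2L))
    ds <- apply(pairs, 1L, function(ij) {
      linkfun(clusters[[ij[1]]], clusters[[ij[2]]])
    })
    cand <- which(ds <= min(ds) + 1e-9)
    keys <- vapply(cand, function(ci) {
      paste(sort(c(reps[pairs[ci, 1]], reps[pairs[ci, 2]])), collapse = "\r")
    }, character(1))
    pick <- cand[order(keys)[1L]]
    i <- pairs[pick, 1]
    j <- pairs[pick, 2]
    merge[step, ] <- sort(c(nodes[[i]], nodes[[j]]))
    height[step] <- ds[pick]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    nodes[[i]] <- step
    reps[i] <- min(reps[i], reps[j])
    clusters[[j]] <- NULL
    nodes <- nodes[-j]
    reps <- reps[-j]
  }
  list(merge = merge, height = cummax(height))
}

# random labeled similarity matrix with unit diagonal
randomSimilarity <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n, -1, 1), n, n)
  s <- (m + t(m)) / 2
  diag(s) <- 1
  labels <- sprintf("L%02d", seq_len(n))
  dimnames(s) <- list(labels, labels)
  s
}

# random in-memory corpus over simple protein/disease pools
randomCorpus <- function(seed, n_abs, n_prot, n_dis) {
  set.seed(seed)
  prots <- sprintf("P%03d", seq_len(n_prot))
  dis <- sprintf("disease_%02d", seq_len(n_dis))
  men <- lapply(seq_len(n_abs), function(i) {
    list(
      proteins = sample(prots, rbinom(1, n_prot, 0.25)),
      diseases = sample(dis, rbinom(1, n_dis, 0.3))
    )
  })
  corpus(sprintf("a%04d", seq_len(n_abs)), men)
}

# small swarm member list drawn from a protein pool
randomSwarms <- function(seed, n_swarms, n_prot, max_size = 5) {
  set.seed(seed)
  prots <- sprintf("P%03d", seq_len(n_prot))
  members <- lapply(seq_len(n_swarms), function(i) {
    sample(prots, sample.int(max_size, 1))
  })
  names(members) <- sprintf("S%02d", seq_len(n_swarms))
  members
}

# a tiny synthetic config that keeps unit tests fast
tinyConfig <- function(seed = 1L, ...) {
  syntheticConfig(
    n_proteins = 400L, n_tissues = 3L, n_processes = 2L, n_diseases = 12L,
    n_functions = 9L, n_mirnas = 9L, n_blocks = 3L, p_in = 0.6,
    p_out = 0.02, n_abstracts = 400L, module_size = 10L, filler = 5L,
    seed = seed, ...
  )
}
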