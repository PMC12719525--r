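# Hierarchical clustering of information spectra with CCSV dendrogram cuts.
#
# CCSV (cluster similarity confidence value) is read as merge similarity on
# a [0, 1]-style scale: clustering runs agglomeratively on distance
# d = 1 - s and each merge records s = 1 - d. A "CCSV threshold > t" cut
# keeps the maximal subtrees all of whose internal merges exceed t.

#' Pairwise similarity matrix between the vectors of a spectrum
#'
#' @param matrix a [SpectrumMatrix-class] or plain labeled numeric matrix.
#' @param metric `"pearson"`, `"spearman"` or `"cosine"`.
#' @param axis `"rows"` (default) to compare row vectors, `"cols"` for
#'   columns.
#' @return list with `labels` and `values` (symmetric matrix, unit
#'   diagonal). Constant vectors under a correlation metric, or any
#'   non-finite input, are errors naming the offending label.
#' @export
similarityMatrix <- function(matrix, metric = c("pearson", "spearman", "cosine"),
                             axis = c("rows", "cols")) {
  metric <- match.arg(metric)
  axis <- match.arg(axis)
  m <- if (is(matrix, "SpectrumMatrix")) matrix@counts else matrix
  if (axis == "cols") m <- t(m)
  if (nrow(m) < 2L) .err("need at least 2 vectors to compare")
  if (any(!is.finite(m))) .err("non-finite values in the input matrix")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  if (metric %in% c("pearson", "spearman")) {
    const <- apply(m, 1L, function(r) diff(range(r)) == 0)
    if (any(const)) {
      .err("constant vector under %s correlation: %s", metric,
           labels[which(const)[1]])
    }
    s <- cor(t(m), method = metric)
  } else {
    nrm <- sqrt(rowSums(m^2))
    zero <- nrm == 0
    if (any(zero)) .err("zero vector under cosine similarity: %s",
                        labels[which(zero)[1]])
    s <- tcrossprod(m / nrm)
  }
  s[s > 1] <- 1
  s[s < -1] <- -1
  diag(s) <- 1
  dimnames(s) <- list(labels, labels)
  list(labels = labels, values = s)
}

# representative of a cluster = its lexicographically smallest leaf label;
# pick, among pairs within tol of the minimal distance, the one whose sorted
# representative pair is lexicographically smallest
.pickMergePair <- function(D, reps, tol = 1e-9) {
  n <- nrow(D)
  dmin <- min(D[upper.tri(D)])
  cand <- which(upper.tri(D) & D <= dmin + tol, arr.ind = TRUE)
  keys <- apply(cand, 1L, function(ij) {
    r <- sort(c(reps[ij[1]], reps[ij[2]]))
    paste(r, collapse = "\r")
  })
  cand[order(keys)[1L], ]
}

#' Agglomerative merge tree on a similarity matrix
#'
#' Runs agglomerative clustering on the distance `d = 1 - s` with the chosen
#' linkage (Lance-Williams updates), recording each merge's similarity
#' `1 - d`. Ties in the minimal distance are broken by the lexicographically
#' smallest pair of cluster representatives (a cluster's representative is
#' its smallest leaf label), making the tree deterministic.
#'
#' @param sim output of [similarityMatrix()] (or a symmetric labeled
#'   similarity matrix).
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @return a [MergeTree-class].
#' @export
hierarchicalMergeTree <- function(sim, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  if (is.list(sim) && !is.null(sim$values)) {
    s <- sim$values
    labels <- sim$labels
  } else {
    s <- as.matrix(sim)
    labels <- rownames(s)
  }
  n <- nrow(s)
  if (n < 2L) .err("need at least 2 leaves to cluster")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- 1 - s
  diag(D) <- Inf

  node <- -seq_len(n)           # hclust convention: leaves negative
  sizes <- rep(1L, n)
  reps <- labels
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  subtrees <- as.list(seq_len(n))   # leaf indices under each active node

  order_of <- vector("list", n)
  for (i in seq_len(n)) order_of[[i]] <- i

  for (step in seq_len(n - 1L)) {
    ij <- .pickMergePair(D, reps)
    i <- min(ij)
    j <- max(ij)
    d <- D[i, j]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- d

    # Lance-Williams update of cluster i as the merged cluster
    ni <- sizes[i]
    nj <- sizes[j]
    drow <- switch(linkage,
      average = (ni * D[i, ] + nj * D[j, ]) / (ni + nj),
      complete = pmax(D[i, ], D[j, ]),
      single = pmin(D[i, ], D[j, ])
    )
    D[i, ] <- drow
    D[, i] <- drow
    D[i, i] <- Inf
    node[i] <- step
    sizes[i] <- ni + nj
    reps[i] <- min(reps[i], reps[j])
    order_of[[i]] <- c(order_of[[i]], order_of[[j]])
    subtrees[[i]] <- c(subtrees[[i]], subtrees[[j]])
    keep <- setdiff(seq_len(nrow(D)), j)
    D <- D[keep, keep, drop = FALSE]
    node <- node[keep]
    sizes <- sizes[keep]
    reps <- reps[keep]
    order_of <- order_of[keep]
    subtrees <- subtrees[keep]
  }
  height <- cummax(height)   # guard tiny non-monotone float noise
  new("MergeTree",
    labels = labels, merge = merge, height = height,
    similarity = 1 - height, order = as.integer(order_of[[1]]),
    linkage = linkage
  )
}

#' Convert a MergeTree to an hclust object
#'
#' @param x a [MergeTree-class].
#' @param ... ignored.
#' @return a [stats::hclust] object (heights are merge distances `1 - s`).
#' @export
as.hclust.MergeTree <- function(x, ...) {
  structure(
    list(merge = x@merge, height = x@height, order = x@order,
         labels = x@labels, method = x@linkage,
         call = match.call(), dist.method = "1 - similarity"),
    class = "hclust"
  )
}

#' Export a MergeTree as a Newick string
#'
#' Branch lengths are on the distance scale `1 - similarity`.
#'
#' @param tree a [MergeTree-class].
#' @param path optional output path; when given, the Newick string is
#'   written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
writeNewick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(as.hclust.MergeTree(tree))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Cut a merge tree at a CCSV threshold
#'
#' Clusters are the maximal subtrees all of whose internal merges have
#' similarity strictly greater than the threshold; leaves not absorbed by
#' any such merge remain singletons. Each cluster's CCSV is its minimum
#' internal merge similarity (1 for singletons). Clusters are ordered and
#' numbered by dendrogram leaf order.
#'
#' @param tree a [MergeTree-class].
#' @param threshold similarity threshold.
#' @return a [ClusterPartition-class].
#' @export
ccsvCut <- function(tree, threshold) {
  n <- length(tree@labels)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  ccsv <- rep(1, n)           # per-root minimum internal merge similarity
  node_root <- integer(n - 1L)   # leaf root representing each merged node
  for (step in seq_len(max(0L, n - 1L))) {
    s <- tree@similarity[step]
    if (s <= threshold) break   # monotone: later merges are no higher
    ch <- tree@merge[step, ]
    roots <- vapply(ch, function(cn) {
      if (cn < 0) find(-cn) else find(node_root[cn])
    }, integer(1))
    r <- roots[1]
    parent[roots[2]] <- r
    ccsv[r] <- min(ccsv[roots[1]], ccsv[roots[2]], s)
    node_root[step] <- r
  }
  root_of <- vapply(seq_len(n), find, integer(1))
  leaf_seq <- tree@order
  cluster_ids <- unique(root_of[leaf_seq])
  clusters <- lapply(cluster_ids, function(r) {
    tree@labels[leaf_seq[root_of[leaf_seq] == r]]
  })
  names(clusters) <- sprintf("C%d", seq_along(clusters))
  new("ClusterPartition",
    threshold = threshold, clusters = clusters,
    ccsv = setNames(ccsv[cluster_ids], names(clusters))
  )
}

#' Two-way clustering of a spectrum matrix
#'
#' Independently clusters rows and columns (for heatmap-style displays) and
#' returns both trees with their leaf orderings.
#'
#' @param matrix a [SpectrumMatrix-class] or plain labeled numeric matrix.
#' @param metric,linkage passed to [similarityMatrix()] /
#'   [hierarchicalMergeTree()].
#' @return list with `row_tree`, `col_tree`, `row_order`, `col_order`.
#' @export
twoWayCluster <- function(matrix, metric = "pearson", linkage = "average") {
  m <- if (is(matrix, "SpectrumMatrix")) matrix@counts else matrix
  if (nrow(m) < 2L || ncol(m) < 2L) .err("need at least a 2 x 2 matrix")
  row_tree <- hierarchicalMergeTree(similarityMatrix(m, metric, "rows"), linkage)
  col_tree <- hierarchicalMergeTree(similarityMatrix(m, metric, "cols"), linkage)
  list(
    row_tree = row_tree, col_tree = col_tree,
    row_order = leafOrder(row_tree), col_order = leafOrder(col_tree)
  )
}

# partitions as named membership vectors over the same label universe
.asMembership <- function(p) {
  if (is(p, "ClusterPartition")) return(membership(p))
  if (is.list(p)) {
    lab <- unlist(p, use.names = FALSE)
    return(setNames(rep(seq_along(p), lengths(p)), lab))
  }
  if (is.null(names(p))) .err("membership vectors must be named")
  setNames(match(p, unique(p)), names(p))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the pair-counting contingency table;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param partition_a,partition_b [ClusterPartition-class] objects, lists of
#'   label sets, or named membership vectors over the same label universe.
#' @return the ARI, a number in `[-1, 1]`.
#' @export
adjustedRand <- function(partition_a, partition_b) {
  a <- .asMembership(partition_a)
  b <- .asMembership(partition_b)
  if (!setequal(names(a), names(b))) {
    .err("partitions are over different label universes")
  }
  b <- b[names(a)]
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  npairs <- choose(n, 2)
  expected <- ai * bj / npairs
  maxi <- (ai + bj) / 2
  if (maxi == expected) return(1)   # both partitions trivial
  (nij - expected) / (maxi - expected)
}
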