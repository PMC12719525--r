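# Protein swarm associations (PSAs), microRNA cluster extraction and
# PSA-to-microRNA-cluster linkage.

#' Extract protein swarm associations from a swarm partition
#'
#' One PSA per cluster of the CCSV-cut partition, numbered in dendrogram
#' leaf order ("PSA1", "PSA2", ...). Each PSA carries its member swarms and
#' the union of their proteins.
#'
#' @param partition a [ClusterPartition-class] over swarm ids (clusters are
#'   already in leaf order when produced by [ccsvCut()]).
#' @param catalog the [SwarmCatalog-class] the swarm ids refer to.
#' @return data.frame with columns `psa_id`, `n_swarms`, `n_proteins`,
#'   `ccsv`, and list-columns `swarms`, `proteins`.
#' @export
extractPsas <- function(partition, catalog) {
  members <- swarmMembers(catalog)
  unknown <- setdiff(unlist(partition@clusters, use.names = FALSE),
                     names(members))
  if (length(unknown)) .err("unknown swarm id: %s", unknown[[1]])
  swarms <- unname(partition@clusters)
  proteins <- lapply(swarms, function(s) {
    sort(unique(unlist(members[s], use.names = FALSE)))
  })
  df <- data.frame(
    psa_id = sprintf("PSA%d", seq_along(swarms)),
    n_swarms = lengths(swarms),
    n_proteins = lengths(proteins),
    ccsv = unname(partition@ccsv),
    stringsAsFactors = FALSE
  )
  df$swarms <- swarms
  df$proteins <- proteins
  df
}

#' Cluster microRNAs by their swarm co-citation profiles
#'
#' Columns of the swarm x microRNA spectrum are clustered with the same
#' similarity/linkage machinery as the swarm side and cut at the CCSV
#' threshold; clusters are labeled "A", "B", ... in dendrogram leaf order.
#'
#' @param spectrum a swarm x microRNA [SpectrumMatrix-class] (or plain
#'   labeled matrix, e.g. an already-transformed one).
#' @param threshold CCSV cut threshold (default 0.67).
#' @param metric,linkage clustering parameters.
#' @param transform `"log1p"` (default) or `"none"` conditioning applied
#'   before similarity.
#' @return list with `clusters` (data.frame: `cluster_id`, `n_members`,
#'   `ccsv`, list-column `members`), `partition` and `tree`.
#' @export
clusterMirnas <- function(spectrum, threshold = 0.67, metric = "pearson",
                          linkage = "average", transform = "log1p") {
  m <- if (is(spectrum, "SpectrumMatrix")) spectrum@counts else spectrum
  if (ncol(m) < 2L) .err("need at least 2 microRNA columns")
  vals <- transformSpectrum(m, method = transform)$values
  tree <- hierarchicalMergeTree(similarityMatrix(vals, metric, "cols"), linkage)
  part <- ccsvCut(tree, threshold)
  labels <- .letterLabels(length(part@clusters))
  clusters <- setNames(part@clusters, labels)
  df <- data.frame(
    cluster_id = labels,
    n_members = lengths(clusters),
    ccsv = unname(part@ccsv),
    stringsAsFactors = FALSE
  )
  df$members <- unname(clusters)
  part2 <- new("ClusterPartition", threshold = part@threshold,
               clusters = clusters, ccsv = setNames(part@ccsv, labels))
  list(clusters = df, partition = part2, tree = tree)
}

#' Link microRNA clusters to protein swarm associations
#'
#' For every (PSA, microRNA cluster) pair, compares the mean co-citation
#' count over the block sub-matrix (PSA member swarms x cluster microRNAs)
#' with the mean over all other cells of the spectrum. A pair is linked when
#' the block mean is positive and at least `factor` times the background
#' mean.
#'
#' @param spectrum the swarm x microRNA [SpectrumMatrix-class]; rows must
#'   cover every PSA member swarm and columns every cluster microRNA.
#' @param psas data.frame from [extractPsas()].
#' @param mirna_clusters data.frame from [clusterMirnas()] (`$clusters`).
#' @param factor linkage enrichment factor (default 2).
#' @return data.frame with one row per (PSA, cluster) pair: `psa_id`,
#'   `mirna_cluster`, `block_mean`, `background_mean`, `enrichment_ratio`,
#'   `linked`.
#' @export
mapMirnaClusters <- function(spectrum, psas, mirna_clusters, factor = 2.0) {
  m <- if (is(spectrum, "SpectrumMatrix")) spectrum@counts else spectrum
  total <- sum(m)
  n_cells <- length(m)
  out <- vector("list", nrow(psas) * nrow(mirna_clusters))
  k <- 0L
  for (i in seq_len(nrow(psas))) {
    rows <- psas$swarms[[i]]
    if (!all(rows %in% rownames(m))) {
      .err("spectrum rows do not cover PSA '%s'", psas$psa_id[i])
    }
    for (j in seq_len(nrow(mirna_clusters))) {
      cols <- mirna_clusters$members[[j]]
      if (!all(cols %in% colnames(m))) {
        .err("spectrum columns do not cover cluster '%s'",
             mirna_clusters$cluster_id[j])
      }
      blk <- m[rows, cols, drop = FALSE]
      nb <- length(blk)
      if (nb == 0L) {
        .err("empty block for (%s, %s)", psas$psa_id[i],
             mirna_clusters$cluster_id[j])
      }
      block_mean <- sum(blk) / nb
      bg_n <- n_cells - nb
      background_mean <- if (bg_n > 0L) (total - sum(blk)) / bg_n else 0
      ratio <- if (background_mean > 0) {
        block_mean / background_mean
      } else if (block_mean > 0) Inf else 0
      k <- k + 1L
      out[[k]] <- data.frame(
        psa_id = psas$psa_id[i],
        mirna_cluster = mirna_clusters$cluster_id[j],
        block_mean = block_mean, background_mean = background_mean,
        enrichment_ratio = ratio,
        linked = block_mean > 0 && ratio >= factor,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Select swarm clusters co-clustered with a named concept
#'
#' Generic seeding rule for concept-focused analyses: given a swarm x
#' concept spectrum and a swarm partition, returns the clusters whose mean
#' count in the named concept column is at least `factor` times the column's
#' overall mean.
#'
#' @param spectrum a [SpectrumMatrix-class] with the concept among its
#'   columns.
#' @param partition a [ClusterPartition-class] over the spectrum rows.
#' @param concept the concept identifier to seed from.
#' @param factor selection factor (default 2).
#' @return character vector of cluster names.
#' @export
selectSwarmClusters <- function(spectrum, partition, concept, factor = 2.0) {
  m <- if (is(spectrum, "SpectrumMatrix")) spectrum@counts else spectrum
  if (!concept %in% colnames(m)) .err("concept '%s' not in spectrum", concept)
  col <- m[, concept]
  overall <- mean(col)
  if (overall == 0) return(character())
  sel <- vapply(partition@clusters, function(lv) {
    mean(col[lv]) >= factor * overall
  }, logical(1))
  names(partition@clusters)[sel]
}
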