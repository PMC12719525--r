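# Overlap enrichment (hypergeometric upper tail + Benjamini-Hochberg FDR)
# and induced-subgraph statistics for protein sets.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the probability of observing at
#' least `k` annotated proteins when drawing `n` from a universe of `N`
#' containing `K` annotated. This is the over-representation statistic behind
#' gene-set "network overlap" enrichment. Delegates to [stats::phyper()],
#' which accumulates the tail stably.
#'
#' @param k observed overlap count.
#' @param K annotation-set size.
#' @param n query-set size.
#' @param N universe size.
#' @return the tail probability.
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    .err("hypergeomTail: need 0 <= k <= min(K, n) and K, n <= N")
  }
  if (k == 0) return(1)
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment, clipped to 1 and returned in input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, parallel to `pvals`.
#' @export
bhFdr <- function(pvals) {
  if (!length(pvals)) return(numeric())
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    .err("p-values must lie in [0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Overlap enrichment of a protein set against an annotation collection
#'
#' Tests every annotation set for over-representation in the query via the
#' hypergeometric upper tail, after intersecting annotation members with the
#' universe. q-values are BH-adjusted across all tested sets of the
#' collection; by default only sets with a non-empty overlap are reported.
#'
#' @param query character vector of protein symbols (must lie in `universe`).
#' @param annotation a [GeneSetCollection-class].
#' @param universe character vector of background protein symbols.
#' @param include_empty report sets with zero overlap too.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   sorted by `q` then `p`.
#' @export
enrichProteinSet <- function(query, annotation, universe,
                             include_empty = FALSE) {
  universe <- unique(normalizeProtein(universe))
  if (!length(universe)) .err("empty universe")
  query <- unique(normalizeProtein(query))
  if (!all(query %in% universe)) .err("query proteins outside the universe")
  terms <- names(annotation@sets)
  res <- lapply(terms, function(tm) {
    members <- intersect(annotation@sets[[tm]], universe)
    k <- length(intersect(query, members))
    data.frame(term = tm, k = k, K = length(members), n = length(query),
               N = length(universe),
               p = hypergeomTail(k, length(members), length(query),
                                 length(universe)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  }
  res$q <- bhFdr(res$p)
  if (!include_empty) res <- res[res$k >= 1L, , drop = FALSE]
  res <- res[order(res$q, res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Induced-subgraph statistics for a protein set
#'
#' Statistics of the subgraph induced by `proteins` on an interaction graph.
#' Proteins absent from the graph are kept as isolated nodes and their count
#' reported, so connectivity claims are made against the full query set.
#'
#' @param graph an [InteractionGraph-class].
#' @param proteins character vector of protein symbols.
#' @return list with `n_nodes`, `n_edges`, `n_components`,
#'   `largest_component_fraction` and `n_missing` (proteins not in the graph).
#' @export
inducedSubgraphStats <- function(graph, proteins) {
  proteins <- unique(normalizeProtein(proteins))
  if (!length(proteins)) {
    return(list(n_nodes = 0L, n_edges = 0L, n_components = 0L,
                largest_component_fraction = NA_real_, n_missing = 0L))
  }
  present <- intersect(proteins, graph@nodes)
  missing <- setdiff(proteins, graph@nodes)
  e <- graph@edges
  keep <- e[, 1] %in% present & e[, 2] %in% present
  sub <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(sub, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = proteins)
  )
  comp <- igraph::components(g)
  list(
    n_nodes = length(proteins),
    n_edges = nrow(sub),
    n_components = comp$no,
    largest_component_fraction = max(comp$csize) / length(proteins),
    n_missing = length(missing)
  )
}
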