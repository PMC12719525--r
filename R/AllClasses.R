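#' @import methods
#' @importFrom stats cor phyper p.adjust setNames runif rbinom
#' @importFrom utils head combn
NULL

#' EntityVocabulary: the entity classes recognized in a corpus
#'
#' Holds the four entity classes used throughout the analysis: protein
#' symbols, disease concepts, immune/biological function concepts, and
#' normalized microRNA identifiers. Classes must be pairwise disjoint after
#' normalization so that a mention resolves to exactly one class.
#'
#' @slot proteins character vector of protein symbols (upper case).
#' @slot diseases character vector of disease concept identifiers.
#' @slot functions character vector of function concept identifiers.
#' @slot microRNAs character vector of normalized microRNA identifiers.
#' @export
setClass("EntityVocabulary",
  representation(
    proteins = "character",
    diseases = "character",
    functions = "character",
    microRNAs = "character"
  )
)

setValidity("EntityVocabulary", function(object) {
  cls <- list(
    proteins = object@proteins, diseases = object@diseases,
    functions = object@functions, microRNAs = object@microRNAs
  )
  for (nm in names(cls)) {
    v <- cls[[nm]]
    if (any(!nzchar(v))) return(sprintf("empty identifier in class '%s'", nm))
    if (anyDuplicated(v)) return(sprintf("duplicated identifier in class '%s'", nm))
  }
  all_ids <- unlist(cls, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    return("entity classes are not pairwise disjoint")
  }
  TRUE
})

#' GeneSetCollection: named sets of protein symbols
#'
#' A collection of named gene sets (tissue proteomes, biological processes,
#' disease or pathway annotation sets) with one free-text description per
#' set, as read from GMT files.
#'
#' @slot sets named list of character vectors (protein symbols, upper case).
#' @slot description named character vector, parallel to `sets`.
#' @export
setClass("GeneSetCollection",
  representation(sets = "list", description = "character")
)

setValidity("GeneSetCollection", function(object) {
  nm <- names(object@sets)
  if (length(object@sets) && (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm)))) {
    return("set names must be unique, non-empty")
  }
  if (!identical(names(object@description), nm)) {
    return("description names must match set names")
  }
  for (s in object@sets) {
    if (!is.character(s)) return("set members must be character")
    if (any(!nzchar(s))) return("empty member identifier")
  }
  TRUE
})

#' Corpus: a collection of pre-annotated abstracts
#'
#' Each abstract carries a unique id and its entity mentions, keyed by entity
#' class ("proteins", "diseases", "functions", "microRNAs"). Mentions are
#' stored as normalized, deduplicated character vectors.
#'
#' @slot ids character vector of abstract ids (unique, original order).
#' @slot mentions list, parallel to `ids`; each element a named list of
#'   character vectors keyed by entity class.
#' @export
setClass("Corpus", representation(ids = "character", mentions = "list"))

setValidity("Corpus", function(object) {
  if (length(object@ids) != length(object@mentions)) {
    return("ids and mentions must have equal length")
  }
  if (anyDuplicated(object@ids)) return("duplicate abstract id")
  if (any(!nzchar(object@ids))) return("empty abstract id")
  TRUE
})

#' InteractionGraph: an undirected protein-protein interaction graph
#'
#' Simple undirected graph over protein symbols; edges are stored as a
#' two-column character matrix in canonical (sorted) order, with no
#' self-loops or duplicate pairs.
#'
#' @slot nodes character vector of protein symbols.
#' @slot edges two-column character matrix of canonical node pairs.
#' @export
setClass("InteractionGraph",
  representation(nodes = "character", edges = "matrix")
)

setValidity("InteractionGraph", function(object) {
  e <- object@edges
  if (ncol(e) != 2L && nrow(e) > 0L) return("edges must have two columns")
  if (anyDuplicated(object@nodes)) return("duplicate node")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) return("self-loop edge")
    if (any(e[, 1] > e[, 2])) return("edge pair not in canonical order")
    key <- paste(e[, 1], e[, 2], sep = "\r")
    if (anyDuplicated(key)) return("duplicate edge")
    if (!all(c(e) %in% object@nodes)) return("edge references unknown node")
  }
  TRUE
})

#' SwarmCatalog: protein swarms indexed by protein
#'
#' The catalog of protein swarms produced by chunking enriched tissue x
#' process overlap modules into groups of at most five proteins. Each swarm
#' keeps its tissue and process labels; `swarm_id` is
#' `"<tissue>|<process>|<k>"`.
#'
#' @slot swarm_id character vector of unique swarm ids.
#' @slot tissue,process character vectors, parallel to `swarm_id`.
#' @slot members list of character vectors (1-5 proteins each).
#' @export
setClass("SwarmCatalog",
  representation(
    swarm_id = "character", tissue = "character",
    process = "character", members = "list"
  )
)

setValidity("SwarmCatalog", function(object) {
  n <- length(object@swarm_id)
  if (length(object@tissue) != n || length(object@process) != n ||
      length(object@members) != n) {
    return("parallel slots of unequal length")
  }
  if (anyDuplicated(object@swarm_id)) return("duplicate swarm id")
  sz <- lengths(object@members)
  if (n && (any(sz < 1L) || any(sz > 5L))) {
    return("swarm sizes must be between 1 and 5")
  }
  TRUE
})

#' SpectrumMatrix: a swarm x concept co-citation count matrix
#'
#' The "information spectrum" matrix: entry (i, j) is the number of abstracts
#' co-mentioning row entity i (a swarm, via its member proteins, or a plain
#' entity) and column concept j. `mode` records the swarm counting semantics:
#' `"any-member"` (an abstract counts if it mentions any swarm member) or
#' `"all-members"` (it must mention every member).
#'
#' @slot counts non-negative integer matrix with unique dimnames.
#' @slot corpus_size integer, the number of abstracts counted over.
#' @slot mode `"any-member"` or `"all-members"`.
#' @export
setClass("SpectrumMatrix",
  representation(counts = "matrix", corpus_size = "integer", mode = "character")
)

setValidity("SpectrumMatrix", function(object) {
  m <- object@counts
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    return("counts must carry row and column labels")
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    return("duplicate row or column label")
  }
  if (length(m) && (any(m < 0) || any(m != round(m)))) {
    return("counts must be non-negative integers")
  }
  if (length(m) && any(m > object@corpus_size)) {
    return("count exceeds corpus size")
  }
  if (!object@mode %in% c("any-member", "all-members")) {
    return("mode must be 'any-member' or 'all-members'")
  }
  TRUE
})

#' MergeTree: an agglomerative dendrogram with per-merge similarity
#'
#' Stores the merge sequence of an agglomerative clustering in the
#' `stats::hclust` convention (negative entries index leaves, positive
#' entries earlier merges). `height` is the merge distance `d = 1 - s`;
#' `similarity` is the CCSV scale `s = 1 - d` at which each merge happened,
#' non-increasing along the sequence for the monotone linkages used here.
#'
#' @slot labels character vector of leaf labels.
#' @slot merge integer matrix (n-1 x 2), hclust convention.
#' @slot height numeric vector of merge distances (non-decreasing).
#' @slot similarity numeric vector, `1 - height`.
#' @slot order integer vector, dendrogram leaf order.
#' @slot linkage character, one of "average", "complete", "single".
#' @export
setClass("MergeTree",
  representation(
    labels = "character", merge = "matrix", height = "numeric",
    similarity = "numeric", order = "integer", linkage = "character"
  )
)

setValidity("MergeTree", function(object) {
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L) return("a tree on n leaves needs n-1 merges")
  if (length(object@height) != n - 1L || length(object@similarity) != n - 1L) {
    return("height/similarity length must be n-1")
  }
  if (n > 2L && any(diff(object@height) < -1e-8)) {
    return("merge heights must be non-decreasing (monotone linkage)")
  }
  kids <- c(object@merge)
  if (anyDuplicated(kids)) return("a node may be used at most once as a child")
  if (!setequal(kids[kids < 0], -seq_len(n))) return("every leaf must be merged")
  if (length(object@order) != n || !setequal(object@order, seq_len(n))) {
    return("order must be a permutation of the leaves")
  }
  TRUE
})

#' ClusterPartition: a dendrogram cut at a CCSV threshold
#'
#' The partition obtained by keeping the maximal subtrees all of whose
#' internal merges exceed the similarity threshold. `ccsv` is each cluster's
#' minimum internal merge similarity (1 for singletons).
#'
#' @slot threshold numeric cut threshold on the similarity scale.
#' @slot clusters named list of character vectors (cluster id -> leaf labels).
#' @slot ccsv named numeric vector, parallel to `clusters`.
#' @export
setClass("ClusterPartition",
  representation(threshold = "numeric", clusters = "list", ccsv = "numeric")
)

setValidity("ClusterPartition", function(object) {
  if (length(object@clusters) != length(object@ccsv)) {
    return("clusters and ccsv must be parallel")
  }
  leaves <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(leaves)) return("clusters must be disjoint")
  multi <- lengths(object@clusters) > 1L
  if (any(multi) && any(object@ccsv[multi] <= object@threshold - 1e-12)) {
    return("multi-member cluster with internal similarity at or below threshold")
  }
  TRUE
})
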