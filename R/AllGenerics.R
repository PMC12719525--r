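# Accessors and show methods for the core classes.

#' @rdname SpectrumMatrix-class
#' @param object,x a SpectrumMatrix (or other object as documented).
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("counts", "SpectrumMatrix", function(object) object@counts)

#' @rdname SpectrumMatrix-class
#' @export
setGeneric("corpusSize", function(object) standardGeneric("corpusSize"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("corpusSize", "SpectrumMatrix", function(object) object@corpus_size)

#' @rdname SpectrumMatrix-class
#' @export
setGeneric("countingMode", function(object) standardGeneric("countingMode"))

#' @rdname SpectrumMatrix-class
#' @export
setMethod("countingMode", "SpectrumMatrix", function(object) object@mode)

#' @rdname GeneSetCollection-class
#' @param object a GeneSetCollection.
#' @export
setGeneric("geneSets", function(object) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(object) object@sets)

#' @rdname Corpus-class
#' @param object a Corpus.
#' @export
setGeneric("abstractIds", function(object) standardGeneric("abstractIds"))

#' @rdname Corpus-class
#' @export
setMethod("abstractIds", "Corpus", function(object) object@ids)

#' @rdname Corpus-class
#' @export
setGeneric("mentions", function(object) standardGeneric("mentions"))

#' @rdname Corpus-class
#' @export
setMethod("mentions", "Corpus", function(object) {
  setNames(object@mentions, object@ids)
})

#' @rdname SwarmCatalog-class
#' @param object a SwarmCatalog.
#' @export
setGeneric("swarmIds", function(object) standardGeneric("swarmIds"))

#' @rdname SwarmCatalog-class
#' @export
setMethod("swarmIds", "SwarmCatalog", function(object) object@swarm_id)

#' @rdname SwarmCatalog-class
#' @export
setGeneric("swarmMembers", function(object) standardGeneric("swarmMembers"))

#' @rdname SwarmCatalog-class
#' @export
setMethod("swarmMembers", "SwarmCatalog", function(object) {
  setNames(object@members, object@swarm_id)
})

#' Protein-to-swarm index of a catalog
#'
#' @param object a SwarmCatalog.
#' @return named list mapping each cataloged protein to the ids of the swarms
#'   containing it.
#' @export
setGeneric("proteinIndex", function(object) standardGeneric("proteinIndex"))

#' @rdname proteinIndex
#' @export
setMethod("proteinIndex", "SwarmCatalog", function(object) {
  df <- data.frame(
    protein = unlist(object@members, use.names = FALSE),
    swarm = rep(object@swarm_id, lengths(object@members)),
    stringsAsFactors = FALSE
  )
  split(df$swarm, df$protein)
})

#' @rdname ClusterPartition-class
#' @param object a ClusterPartition (or MergeTree for `clusterCcsv`-free generics).
#' @export
setGeneric("clusterMembers", function(object) standardGeneric("clusterMembers"))

#' @rdname ClusterPartition-class
#' @export
setMethod("clusterMembers", "ClusterPartition", function(object) object@clusters)

#' @rdname ClusterPartition-class
#' @export
setGeneric("clusterCcsv", function(object) standardGeneric("clusterCcsv"))

#' @rdname ClusterPartition-class
#' @export
setMethod("clusterCcsv", "ClusterPartition", function(object) object@ccsv)

#' Membership vector of a partition
#'
#' @param object a ClusterPartition.
#' @return named integer vector: for every leaf, the index of its cluster.
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname membership
#' @export
setMethod("membership", "ClusterPartition", function(object) {
  lab <- unlist(object@clusters, use.names = FALSE)
  setNames(rep(seq_along(object@clusters), lengths(object@clusters)), lab)
})

#' @rdname MergeTree-class
#' @param object a MergeTree.
#' @export
setGeneric("leafOrder", function(object) standardGeneric("leafOrder"))

#' @rdname MergeTree-class
#' @export
setMethod("leafOrder", "MergeTree", function(object) {
  object@labels[object@order]
})

#' @rdname MergeTree-class
#' @export
setGeneric("mergeSimilarity", function(object) standardGeneric("mergeSimilarity"))

#' @rdname MergeTree-class
#' @export
setMethod("mergeSimilarity", "MergeTree", function(object) object@similarity)

setMethod("show", "EntityVocabulary", function(object) {
  cat("EntityVocabulary:",
      length(object@proteins), "proteins,",
      length(object@diseases), "diseases,",
      length(object@functions), "functions,",
      length(object@microRNAs), "microRNAs\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets")
  if (length(object@sets)) {
    cat("; sizes", paste(range(lengths(object@sets)), collapse = "-"))
  }
  cat("\n")
})

setMethod("show", "Corpus", function(object) {
  cat("Corpus of", length(object@ids), "annotated abstracts\n")
})

setMethod("show", "InteractionGraph", function(object) {
  cat("InteractionGraph:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
})

setMethod("show", "SwarmCatalog", function(object) {
  cat("SwarmCatalog:", length(object@swarm_id), "swarms over",
      length(unique(unlist(object@members, use.names = FALSE))), "proteins\n")
})

setMethod("show", "SpectrumMatrix", function(object) {
  cat("SpectrumMatrix (", object@mode, "): ",
      nrow(object@counts), " rows x ", ncol(object@counts),
      " concepts, corpus size ", object@corpus_size, "\n", sep = "")
})

setMethod("show", "MergeTree", function(object) {
  cat("MergeTree (", object@linkage, " linkage): ",
      length(object@labels), " leaves, merge similarity range [",
      sprintf("%.3f", min(object@similarity)), ", ",
      sprintf("%.3f", max(object@similarity)), "]\n", sep = "")
})

setMethod("show", "ClusterPartition", function(object) {
  cat("ClusterPartition at threshold", object@threshold, ":",
      length(object@clusters), "clusters over",
      sum(lengths(object@clusters)), "leaves\n")
})

#' Number of abstracts in a corpus
#' @param x a Corpus.
#' @export
setMethod("length", "Corpus", function(x) length(x@ids))
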