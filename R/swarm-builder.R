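# Swarm construction: tissue x process overlap modules, enrichment-filtered
# and chunked into protein swarms of at most five members.

#' Overlap module between a tissue proteome and a biological process
#'
#' Computes the exact intersection of the two sets and the upper-tail
#' hypergeometric probability of an overlap at least this large, drawing
#' `|tissue|` proteins from a universe of `universe_size` containing
#' `|process|` annotated proteins.
#'
#' @param tissue_set,process_set character vectors of protein symbols.
#' @param universe_size integer universe size (>= the union of both sets).
#' @param tissue,process optional set names carried into the result.
#' @return list with elements `tissue`, `process`, `members`,
#'   `enrichment_p` and `empty` (flag for a void overlap).
#' @export
moduleOverlap <- function(tissue_set, process_set, universe_size,
                          tissue = "tissue", process = "process") {
  tissue_set <- unique(normalizeProtein(tissue_set))
  process_set <- unique(normalizeProtein(process_set))
  u <- length(union(tissue_set, process_set))
  if (universe_size < u) {
    .err("universe_size (%d) smaller than the union of the two sets (%d)",
         universe_size, u)
  }
  members <- sort(intersect(tissue_set, process_set))
  p <- hypergeomTail(length(members), length(process_set),
                     length(tissue_set), universe_size)
  list(tissue = tissue, process = process, members = members,
       enrichment_p = p, empty = length(members) == 0L)
}

#' Partition module members into protein swarms
#'
#' Members are sorted lexicographically and chunked greedily into groups of
#' `max_size`; the last chunk holds the remainder, giving
#' `ceiling(n / max_size)` swarms. The rule is deterministic so that a
#' catalog is reproducible regardless of input order.
#'
#' @param module list as returned by [moduleOverlap()].
#' @param max_size maximum swarm size (default 5).
#' @return list of swarms, each a list with `swarm_id`, `tissue`, `process`,
#'   `members`; empty list for an empty module.
#' @export
partitionIntoSwarms <- function(module, max_size = 5L) {
  members <- sort(module$members)
  n <- length(members)
  if (n == 0L) return(list())
  chunk <- ceiling(seq_len(n) / max_size)
  lapply(seq_len(max(chunk)), function(k) {
    list(
      swarm_id = sprintf("%s|%s|%d", module$tissue, module$process, k),
      tissue = module$tissue, process = module$process,
      members = members[chunk == k]
    )
  })
}

#' Build a swarm catalog from tissue and process collections
#'
#' All tissue x process pairs are intersected; overlap enrichment p-values
#' are adjusted with Benjamini-Hochberg across every pair, and non-empty
#' modules with `q <= q_threshold` are chunked into swarms of at most five
#' proteins via [partitionIntoSwarms()].
#'
#' @param tissues,processes [GeneSetCollection-class] objects.
#' @param universe character vector of protein symbols forming the
#'   enrichment background.
#' @param q_threshold BH-FDR admission threshold for modules (default 0.05).
#' @param max_size maximum swarm size.
#' @return a [SwarmCatalog-class]; empty (with a warning) if either
#'   collection is empty.
#' @export
buildSwarmCatalog <- function(tissues, processes, universe,
                              q_threshold = 0.05, max_size = 5L) {
  stopifnot(is(tissues, "GeneSetCollection"), is(processes, "GeneSetCollection"))
  universe <- unique(normalizeProtein(universe))
  empty_cat <- new("SwarmCatalog", swarm_id = character(),
                   tissue = character(), process = character(),
                   members = list())
  if (!length(tissues@sets) || !length(processes@sets)) {
    warning("empty gene-set collection: returning an empty catalog",
            call. = FALSE)
    return(empty_cat)
  }
  t_names <- sort(names(tissues@sets))
  p_names <- sort(names(processes@sets))
  grid <- expand.grid(tissue = t_names, process = p_names,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  modules <- lapply(seq_len(nrow(grid)), function(i) {
    ts <- intersect(tissues@sets[[grid$tissue[i]]], universe)
    ps <- intersect(processes@sets[[grid$process[i]]], universe)
    moduleOverlap(ts, ps, length(universe),
                  tissue = grid$tissue[i], process = grid$process[i])
  })
  pvals <- vapply(modules, `[[`, numeric(1), "enrichment_p")
  qvals <- bhFdr(pvals)
  keep <- which(qvals <= q_threshold & !vapply(modules, `[[`, logical(1), "empty"))
  swarms <- unlist(lapply(keep, function(i) {
    partitionIntoSwarms(modules[[i]], max_size = max_size)
  }), recursive = FALSE)
  if (!length(swarms)) return(empty_cat)
  new("SwarmCatalog",
    swarm_id = vapply(swarms, `[[`, "", "swarm_id"),
    tissue = vapply(swarms, `[[`, "", "tissue"),
    process = vapply(swarms, `[[`, "", "process"),
    members = lapply(swarms, `[[`, "members")
  )
}

#' Write a swarm catalog as TSV
#'
#' Columns: swarm_id, tissue, process, members (comma-joined).
#'
#' @param catalog a [SwarmCatalog-class].
#' @param path output path.
#' @export
writeSwarmCatalog <- function(catalog, path) {
  df <- data.frame(
    swarm_id = catalog@swarm_id, tissue = catalog@tissue,
    process = catalog@process,
    members = vapply(catalog@members, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a swarm catalog written by [writeSwarmCatalog()]
#'
#' @param path path to the TSV file.
#' @return a [SwarmCatalog-class].
#' @export
readSwarmCatalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  new("SwarmCatalog",
    swarm_id = df$swarm_id, tissue = df$tissue, process = df$process,
    members = strsplit(as.character(df$members), ",", fixed = TRUE)
  )
}
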