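# Co-citation frequency counting: information-spectrum matrices between
# swarms (or plain entities) and concept vocabularies.

# abstract x entity sparse incidence matrix for the given entity ids,
# pooled across all mention classes (classes are disjoint by construction)
.incidenceMatrix <- function(corp, entities) {
  n_abs <- length(corp@ids)
  ent_index <- seq_along(entities)
  names(ent_index) <- entities
  hit_list <- lapply(seq_len(n_abs), function(i) {
    m <- unlist(corp@mentions[[i]], use.names = FALSE)
    unname(ent_index[m[m %in% entities]])
  })
  jj <- unlist(hit_list, use.names = FALSE)
  ii <- rep.int(seq_len(n_abs), lengths(hit_list))
  if (is.null(jj)) jj <- integer(0)
  Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                       dims = c(n_abs, length(entities)),
                       dimnames = list(corp@ids, entities))
}

# rows argument -> named list of member sets
.rowsAsMembers <- function(rows) {
  if (is(rows, "SwarmCatalog")) {
    return(setNames(rows@members, rows@swarm_id))
  }
  if (is.character(rows)) {
    return(setNames(as.list(rows), rows))
  }
  if (is.list(rows)) {
    if (is.null(names(rows))) .err("row member lists must be named")
    return(rows)
  }
  .err("rows must be a SwarmCatalog, a character vector or a named list")
}

#' Co-citation count of one swarm with one concept
#'
#' Number of abstracts that mention the concept together with the swarm:
#' under `"any-member"` at least one swarm member must be mentioned, under
#' `"all-members"` every member. Counting is binary per abstract (an
#' abstract contributes at most 1 regardless of how often it mentions the
#' entities).
#'
#' @param corpus a [Corpus-class].
#' @param swarm_members non-empty character vector of protein symbols.
#' @param concept a single concept identifier.
#' @param mode `"any-member"` (default) or `"all-members"`.
#' @return integer count.
#' @export
cocitationCount <- function(corpus, swarm_members, concept,
                            mode = c("any-member", "all-members")) {
  mode <- match.arg(mode)
  swarm_members <- unique(normalizeProtein(swarm_members))
  if (!length(swarm_members)) .err("empty swarm member set")
  m <- buildSpectrumMatrix(corpus,
                           rows = setNames(list(swarm_members), "s"),
                           concepts = concept, mode = mode)
  as.integer(m@counts[1, 1])
}

#' Build an information-spectrum matrix
#'
#' Entry (i, j) is the number of abstracts co-mentioning row i and concept j
#' (see [cocitationCount()] for the swarm semantics). The computation indexes
#' abstracts by entity (a sparse abstract-by-entity incidence matrix and a
#' cross-product), which is exactly equivalent to the brute-force double
#' loop over pairs and abstracts.
#'
#' @param corpus a [Corpus-class].
#' @param rows a [SwarmCatalog-class], a character vector of plain entity
#'   ids, or a named list of protein member sets.
#' @param concepts character vector of concept identifiers (any entity
#'   class).
#' @param mode `"any-member"` or `"all-members"` swarm counting semantics.
#' @return a [SpectrumMatrix-class].
#' @export
buildSpectrumMatrix <- function(corpus, rows, concepts,
                                mode = c("any-member", "all-members")) {
  mode <- match.arg(mode)
  members <- .rowsAsMembers(rows)
  if (!length(members)) .err("no rows to count")
  if (!length(concepts)) .err("no concepts to count")
  if (anyDuplicated(names(members))) .err("duplicate row labels")
  if (anyDuplicated(concepts)) .err("duplicate concept labels")
  if (any(lengths(members) == 0L)) .err("empty swarm member set")

  proteins <- unique(unlist(members, use.names = FALSE))
  P <- .incidenceMatrix(corpus, proteins)          # abstracts x proteins
  C <- .incidenceMatrix(corpus, concepts)          # abstracts x concepts
  S <- Matrix::sparseMatrix(                       # proteins x rows
    i = match(unlist(members, use.names = FALSE), proteins),
    j = rep(seq_along(members), lengths(members)),
    x = 1, dims = c(length(proteins), length(members)),
    dimnames = list(proteins, names(members))
  )
  hits <- P %*% S                                   # abstracts x rows
  A <- if (mode == "any-member") {
    hits > 0
  } else {
    t(t(as.matrix(hits)) == lengths(members))
  }
  A <- Matrix::Matrix(A * 1, sparse = TRUE)
  cnt <- as.matrix(Matrix::crossprod(A, C))         # rows x concepts
  storage.mode(cnt) <- "integer"
  dimnames(cnt) <- list(names(members), concepts)
  new("SpectrumMatrix", counts = cnt,
      corpus_size = length(corpus@ids), mode = mode)
}

#' Condition a spectrum matrix for clustering
#'
#' Optionally drops sparse rows (row total below `min_row_total`) and
#' applies an elementwise `log1p` variance-stabilising transform, the
#' default conditioning before similarity computation on heavy-tailed
#' co-citation counts.
#'
#' @param spectrum a [SpectrumMatrix-class] or plain labeled matrix.
#' @param method `"log1p"` or `"none"`.
#' @param min_row_total rows with a smaller total are dropped (default 0).
#' @return list with `values` (transformed numeric matrix, labels
#'   preserved), `kept` and `dropped` (row labels).
#' @export
transformSpectrum <- function(spectrum, method = c("log1p", "none"),
                              min_row_total = 0) {
  method <- match.arg(method)
  if (min_row_total < 0) .err("min_row_total must be >= 0")
  m <- if (is(spectrum, "SpectrumMatrix")) spectrum@counts else spectrum
  totals <- rowSums(m)
  keep <- totals >= min_row_total
  out <- m[keep, , drop = FALSE]
  if (method == "log1p") out <- log1p(out)
  list(values = out, kept = rownames(m)[keep], dropped = rownames(m)[!keep])
}
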