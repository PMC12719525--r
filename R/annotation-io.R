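# Readers and writers for the external formats: GMT gene sets, JSONL
# annotated corpora, TSV edge lists and TSV labeled matrices.

#' Construct an entity vocabulary
#'
#' Identifiers are normalized (proteins upper-cased, microRNAs lower-cased
#' with a "mir-" prefix) and deduplicated. The four classes must be pairwise
#' disjoint after normalization.
#'
#' @param proteins,diseases,functions,microRNAs character vectors.
#' @return an [EntityVocabulary-class].
#' @export
entityVocabulary <- function(proteins = character(), diseases = character(),
                             functions = character(), microRNAs = character()) {
  new("EntityVocabulary",
    proteins = unique(normalizeProtein(proteins)),
    diseases = unique(trimws(as.character(diseases))),
    functions = unique(trimws(as.character(functions))),
    microRNAs = unique(normalizeMirna(microRNAs))
  )
}

#' Read a GMT gene-set file
#'
#' Each line is `name<TAB>description<TAB>member1<TAB>member2...`. Member
#' symbols are upper-cased and deduplicated within a set. A line with fewer
#' than two tab-separated fields, or a repeated set name, is an error. A set
#' with no members is kept (flagged by its zero length).
#'
#' @param path path to a GMT file.
#' @return a [GeneSetCollection-class].
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) .err("gene-set file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descr <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      .err("malformed GMT line %d: fewer than 2 tab-separated fields", i)
    }
    nm <- trimws(f[[1]])
    if (nm %in% names(sets)) .err("duplicate set name '%s' (line %d)", nm, i)
    members <- f[-(1:2)]
    members <- unique(normalizeProtein(members[nzchar(members)]))
    sets[[nm]] <- members
    descr[[nm]] <- f[[2]]
  }
  new("GeneSetCollection", sets = sets, description = descr)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @export
writeGeneSets <- function(collection, path) {
  stopifnot(is(collection, "GeneSetCollection"))
  lines <- vapply(names(collection@sets), function(nm) {
    paste(c(nm, collection@description[[nm]], collection@sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.MENTION_CLASSES <- c("proteins", "diseases", "functions", "microRNAs")

.normalizeMentions <- function(m) {
  out <- list(
    proteins = character(), diseases = character(),
    functions = character(), microRNAs = character()
  )
  for (cls in intersect(names(m), .MENTION_CLASSES)) {
    v <- as.character(unlist(m[[cls]], use.names = FALSE))
    v <- v[nzchar(v)]
    v <- switch(cls,
      proteins = normalizeProtein(v),
      microRNAs = normalizeMirna(v),
      trimws(v)
    )
    out[[cls]] <- sort(unique(v))
  }
  out
}

#' Read a JSONL annotated-abstract corpus
#'
#' One JSON object per line: `{"id": "...", "entities": {"proteins": [...],
#' "diseases": [...], "functions": [...], "microRNAs": [...]}}`. Mention
#' arrays are normalized and deduplicated into sets; record order is
#' preserved. When a vocabulary is supplied, mentions that do not resolve
#' against it are dropped with one summary warning.
#'
#' @param path path to a JSONL file.
#' @param vocabulary optional [EntityVocabulary-class] used to resolve
#'   mentions.
#' @return a [Corpus-class].
#' @export
readCorpus <- function(path, vocabulary = NULL) {
  if (!file.exists(path)) .err("corpus file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  ids <- character(length(lines))
  men <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE)
    if (is.null(rec$id) || !nzchar(rec$id)) {
      .err("corpus record %d is missing an 'id'", i)
    }
    ids[[i]] <- as.character(rec$id)
    men[[i]] <- .normalizeMentions(if (is.null(rec$entities)) list() else rec$entities)
  }
  if (anyDuplicated(ids)) {
    .err("duplicate abstract id '%s'", ids[anyDuplicated(ids)][1])
  }
  corpus <- new("Corpus", ids = ids, mentions = men)
  if (!is.null(vocabulary)) corpus <- resolveMentions(corpus, vocabulary)
  corpus
}

#' Construct a corpus in memory
#'
#' @param ids character vector of abstract ids.
#' @param mentions list of named lists of mention vectors, parallel to `ids`.
#' @return a [Corpus-class].
#' @export
corpus <- function(ids, mentions) {
  new("Corpus", ids = as.character(ids),
      mentions = lapply(mentions, .normalizeMentions))
}

#' Drop mentions that do not resolve against a vocabulary
#'
#' Unresolvable mentions are removed (corpora and vocabularies evolve
#' independently); one warning summarises how many were dropped.
#'
#' @param corpus a [Corpus-class].
#' @param vocabulary an [EntityVocabulary-class].
#' @return the filtered [Corpus-class].
#' @export
resolveMentions <- function(corpus, vocabulary) {
  known <- list(
    proteins = vocabulary@proteins, diseases = vocabulary@diseases,
    functions = vocabulary@functions, microRNAs = vocabulary@microRNAs
  )
  dropped <- 0L
  men <- lapply(corpus@mentions, function(m) {
    for (cls in .MENTION_CLASSES) {
      keep <- m[[cls]] %in% known[[cls]]
      dropped <<- dropped + sum(!keep)
      m[[cls]] <- m[[cls]][keep]
    }
    m
  })
  if (dropped > 0L) {
    warning(sprintf("dropped %d unresolvable mentions", dropped), call. = FALSE)
  }
  new("Corpus", ids = corpus@ids, mentions = men)
}

#' Write a corpus as JSONL
#'
#' @param corpus a [Corpus-class].
#' @param path output path.
#' @export
writeCorpus <- function(corpus, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(corpus@ids)) {
    m <- corpus@mentions[[i]]
    m <- m[lengths(m) > 0L]
    rec <- list(id = corpus@ids[[i]], entities = m)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a TSV protein-protein edge list
#'
#' Two symbol columns, optional header (detected when the first line repeats
#' no symbol seen as data would — a line is treated as a header when either
#' field matches common header words). Self-loops keep the node but drop the
#' edge; duplicate pairs (in either orientation) are collapsed. Counts of
#' discarded lines are reported via a message.
#'
#' @param path path to the TSV file.
#' @param header logical; `TRUE` to skip the first line.
#' @return an [InteractionGraph-class].
#' @export
readEdgeList <- function(path, header = FALSE) {
  if (!file.exists(path)) .err("edge list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (header && length(lines)) lines <- lines[-1]
  if (!length(lines)) return(interactionGraph(character(), NULL))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    .err("edge-list line %d does not have exactly 2 columns", bad[[1]])
  }
  a <- normalizeProtein(vapply(parts, `[[`, "", 1L))
  b <- normalizeProtein(vapply(parts, `[[`, "", 2L))
  nodes <- unique(c(a, b))
  loops <- a == b
  pairs <- .canonicalPairs(a[!loops], b[!loops])
  key <- paste(pairs[, 1], pairs[, 2], sep = "\r")
  dup <- duplicated(key)
  if (any(loops) || any(dup)) {
    message(sprintf("readEdgeList: discarded %d self-loops, %d duplicate pairs",
                    sum(loops), sum(dup)))
  }
  interactionGraph(nodes, pairs[!dup, , drop = FALSE])
}

#' Construct an interaction graph
#'
#' @param nodes character vector of protein symbols.
#' @param edges two-column character matrix or data.frame of node pairs (any
#'   orientation), or `NULL` for an edgeless graph.
#' @return an [InteractionGraph-class].
#' @export
interactionGraph <- function(nodes, edges = NULL) {
  nodes <- unique(normalizeProtein(nodes))
  if (is.null(edges) || NROW(edges) == 0L) {
    e <- matrix(character(), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    a <- normalizeProtein(edges[, 1])
    b <- normalizeProtein(edges[, 2])
    keep <- a != b
    e <- .canonicalPairs(a[keep], b[keep])
    e <- e[!duplicated(paste(e[, 1], e[, 2], sep = "\r")), , drop = FALSE]
    nodes <- unique(c(nodes, c(e)))
  }
  new("InteractionGraph", nodes = nodes, edges = e)
}

#' Write a labeled numeric matrix as TSV
#'
#' Writes a header row of column labels (first cell empty) and one row per
#' matrix row with the row label in the first column. Integer matrices
#' round-trip losslessly through [readMatrixTsv()].
#'
#' @param matrix numeric matrix with unique row and column labels.
#' @param path output path.
#' @export
writeMatrixTsv <- function(matrix, path) {
  rn <- rownames(matrix)
  cn <- colnames(matrix)
  if (nrow(matrix) && is.null(rn)) .err("matrix has no row labels")
  if (ncol(matrix) && is.null(cn)) .err("matrix has no column labels")
  if (anyDuplicated(rn) || anyDuplicated(cn)) .err("duplicate matrix labels")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("", cn), collapse = "\t"), con)
  if (nrow(matrix)) {
    body <- apply(matrix, 1L, function(r) {
      paste(format(r, trim = TRUE, scientific = FALSE, digits = 15),
            collapse = "\t")
    })
    writeLines(paste(rn, body, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a labeled matrix written by [writeMatrixTsv()]
#'
#' @param path path to the TSV file.
#' @return numeric matrix with dimnames.
#' @export
readMatrixTsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) .err("empty matrix file: %s", path)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  cn <- hdr[-1]
  body <- lines[-1]
  m <- matrix(numeric(), nrow = length(body), ncol = length(cn))
  rn <- character(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[[i]], "\t", fixed = TRUE)[[1]]
    rn[[i]] <- f[[1]]
    m[i, ] <- as.numeric(f[-1])
  }
  dimnames(m) <- list(rn, cn)
  m
}

#' Construct a gene-set collection in memory
#'
#' @param sets named list of character vectors of protein symbols.
#' @param description optional named character vector of set descriptions.
#' @return a [GeneSetCollection-class].
#' @export
geneSetCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(s) unique(normalizeProtein(s)))
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  }
  new("GeneSetCollection", sets = sets,
      description = description[names(sets)])
}
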