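# Internal helpers: identifier normalization and small utilities.

#' Normalize protein symbols
#'
#' Protein symbols are upper-cased and whitespace-trimmed so that mixed-case
#' mentions of the same gene ("akt1", "AKT1") collapse to one identifier.
#'
#' @param x character vector of protein symbols.
#' @return character vector of normalized symbols.
#' @export
normalizeProtein <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Normalize microRNA identifiers
#'
#' microRNA names are lower-cased, an optional species prefix ("hsa-") is
#' stripped, and a canonical "mir-" prefix is enforced ("miR-146a-5p" becomes
#' "mir-146a-5p", "let-7a" becomes "mir-let-7a"). Arm suffixes ("-3p"/"-5p")
#' are preserved, and an armless name is a distinct identifier from its armed
#' forms: no arm inference is performed. The transform is idempotent.
#'
#' @param x character vector of microRNA names.
#' @return character vector of normalized identifiers.
#' @export
normalizeMirna <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- sub("^hsa-", "", x)
  has_prefix <- startsWith(x, "mir-")
  bare <- !has_prefix & grepl("^mir[0-9a-z]", x)
  x[bare] <- sub("^mir", "mir-", x[bare])
  rest <- !startsWith(x, "mir-")
  x[rest] <- paste0("mir-", x[rest])
  x
}

# stop() with a consistent prefix-free message built by sprintf
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# canonical unordered pair matrix: two-column character matrix, each row sorted
.canonicalPairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  cbind(a, b, deparse.level = 0)
}

# deterministic letter-style labels: A..Z, AA, AB, ...
.letterLabels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- n - 26L
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS)[seq_len(extra)])
}
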