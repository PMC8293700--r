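#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions and substitutions
#' transforming one string into the other. Operates on Unicode code points,
#' so an accented letter counts as one unit. Vectorized with the usual
#' recycling rules.
#'
#' @param a,b Character vectors (recycled to a common length). `NA` values
#'   are not allowed.
#' @return Integer vector of edit distances.
#' @export
#' @examples
#' levenshtein("kitten", "sitting")
#' levenshtein("hipercalemia", "hipercalcemia")
levenshtein <- function(a, b) {
  if (anyNA(a) || anyNA(b)) abort("NA strings are not allowed")
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  lev_pairs_cpp(lapply(a, utf8ToInt), lapply(b, utf8ToInt))
}

#' Levenshtein distances between all pairs of two string sets
#'
#' @param a,b Character vectors.
#' @return Integer matrix of dimension `length(a)` by `length(b)`.
#' @export
levenshtein_matrix <- function(a, b) {
  if (anyNA(a) || anyNA(b)) abort("NA strings are not allowed")
  m <- lev_cross_cpp(lapply(as.character(a), utf8ToInt),
                     lapply(as.character(b), utf8ToInt))
  dimnames(m) <- list(a, b)
  m
}

#' Percent similarity between two strings
#'
#' The score that drives every matching rule:
#' `floor((1 - d / max(|a|, |b|)) * 100)` where `d` is the Levenshtein
#' distance. The percent is truncated, not rounded — the only convention
#' consistent with both printed near-miss scores (1 edit over lengths 12/13
#' gives 92, 1 edit over 10/11 gives 90). Two empty strings score 100. The
#' score is 100 exactly when the strings are equal, which makes the
#' 100-percent match test equivalent to string equality on normalized input.
#'
#' @param a,b Character vectors of already-normalized terms (recycled).
#' @return Integer vector of scores in `[0, 100]`.
#' @export
#' @examples
#' similarity_percent("hipercalemia", "hipercalcemia") # 92
#' similarity_percent("referencia", "preferencia")     # 90
similarity_percent <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- levenshtein(a, b)
  len <- pmax(nchar(a, type = "chars"), nchar(b, type = "chars"))
  out <- rep(100L, n)
  nz <- len > 0L
  # integer arithmetic: floor((1 - d/len) * 100) == ((len - d) * 100) %/% len
  out[nz] <- as.integer(((len[nz] - d[nz]) * 100L) %/% len[nz])
  out
}
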