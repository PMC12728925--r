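# String-edit similarity used by the Levenshtein rediscovery oracle.
# Distances come from utils::adist (insert/delete/substitute, unit costs).

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions and
#' substitutions turning `a` into `b`, computed elementwise with recycling.
#'
#' @param a,b character vectors.
#' @return integer vector of distances.
#' @export
levenshtein_distance <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0) return(integer())
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- utils::adist(a[i], b[i])[1, 1]
  d
}

#' Cross matrix of Levenshtein distances
#'
#' @param a,b character vectors.
#' @return integer matrix, `length(a)` rows by `length(b)` columns.
#' @export
levenshtein_matrix <- function(a, b) {
  utils::adist(as.character(a), as.character(b))
}

#' Normalized Levenshtein string similarity
#'
#' `1 - LD(a, b) / max(nchar(a), nchar(b))`, the standard normalized edit
#' similarity on the character level. Two empty strings have similarity 1;
#' the value is symmetric, lies in `[0, 1]` and equals 1 only on equality.
#'
#' @param a,b character vectors (elementwise with recycling).
#' @return numeric vector of similarities.
#' @export
levenshtein_similarity <- function(a, b) {
  n <- max(length(a), length(b))
  if (n == 0) return(numeric())
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- levenshtein_distance(a, b)
  m <- pmax(nchar(a), nchar(b))
  ifelse(m == 0, 1, 1 - d / m)
}

# similarity of many strings against many targets in one adist call
.lev_sim_cross <- function(strings, targets) {
  if (length(strings) == 0) {
    return(matrix(numeric(), 0, length(targets)))
  }
  d <- utils::adist(strings, targets)
  m <- outer(nchar(strings), nchar(targets), pmax)
  s <- ifelse(m == 0, 1, 1 - d / m)
  matrix(s, nrow = length(strings))
}
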