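# Diversity filter: the first occurrence of a canonical SMILES keeps its
# reward; every repeat is rewarded 0. The memory grows monotonically over a
# run (environment-backed so repeated application is O(1) per molecule).

#' Create an empty diversity-filter memory
#'
#' @return a `df_memory` object.
#' @export
df_memory <- function() {
  structure(list(seen = new.env(parent = emptyenv(), hash = TRUE)),
            class = "df_memory")
}

#' Apply the diversity filter to rewards
#'
#' First occurrences pass unchanged and are recorded; repeats (by canonical
#' SMILES, so "OCC" after "CCO" counts as a repeat) are zeroed. `NA`
#' canonical SMILES (invalid molecules) pass through unrecorded — their
#' reward is already 0.
#'
#' Note the memory environment is updated in place.
#'
#' @param mem a [df_memory()].
#' @param canonical character vector of canonical SMILES (`NA` allowed).
#' @param reward numeric vector of rewards, recycled to the same length.
#' @return numeric vector of possibly-zeroed rewards.
#' @export
apply_diversity_filter <- function(mem, canonical, reward) {
  stopifnot(inherits(mem, "df_memory"))
  n <- length(canonical)
  reward <- rep_len(reward, n)
  out <- reward
  for (i in seq_len(n)) {
    ci <- canonical[i]
    if (is.na(ci)) next
    if (exists(ci, envir = mem$seen, inherits = FALSE)) {
      out[i] <- 0
    } else {
      assign(ci, TRUE, envir = mem$seen)
    }
  }
  out
}

#' Number of distinct molecules a diversity filter has seen
#'
#' @param mem a [df_memory()].
#' @return integer count.
#' @export
df_size <- function(mem) {
  length(ls(mem$seen, all.names = TRUE))
}
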