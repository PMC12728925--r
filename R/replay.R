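# Replay buffer of high-reward molecules: one entry per canonical SMILES
# (best reward kept), bounded capacity with lowest-reward eviction, and
# reward-proportional prioritized sampling.

#' Create an empty replay buffer
#'
#' @param capacity maximum number of stored molecules.
#' @return a `replay_buffer` object.
#' @export
replay_buffer <- function(capacity = 100L) {
  structure(list(capacity = as.integer(capacity),
                 smiles = character(),
                 reward = numeric(),        # raw reward; sampling priority
                 shaped = numeric(),
                 seqs = list()),
            class = "replay_buffer")
}

#' @export
print.replay_buffer <- function(x, ...) {
  cat("<replay_buffer> ", length(x$smiles), "/", x$capacity, " entries\n",
      sep = "")
  invisible(x)
}

#' Insert a trajectory into a replay buffer
#'
#' Deduplicates by canonical SMILES keeping the highest-reward copy, and
#' evicts the lowest-reward entry when over capacity. Invalid molecules
#' (`NA` canonical SMILES) are never inserted.
#'
#' @param buf a [replay_buffer()].
#' @param smiles canonical SMILES of the molecule (`NA` is a no-op).
#' @param reward raw reward (the sampling priority).
#' @param seq token-index sequence of the trajectory.
#' @param shaped shaped reward stored alongside (defaults to `reward`).
#' @return the updated buffer.
#' @export
buffer_insert <- function(buf, smiles, reward, seq, shaped = reward) {
  stopifnot(inherits(buf, "replay_buffer"))
  if (is.na(smiles)) return(buf)
  at <- match(smiles, buf$smiles)
  if (!is.na(at)) {
    if (reward > buf$reward[at]) {
      buf$reward[at] <- reward
      buf$shaped[at] <- shaped
      buf$seqs[[at]] <- seq
    }
    return(buf)
  }
  buf$smiles <- c(buf$smiles, smiles)
  buf$reward <- c(buf$reward, reward)
  buf$shaped <- c(buf$shaped, shaped)
  buf$seqs <- c(buf$seqs, list(seq))
  if (length(buf$smiles) > buf$capacity) {
    drop <- which.min(buf$reward)
    buf$smiles <- buf$smiles[-drop]
    buf$reward <- buf$reward[-drop]
    buf$shaped <- buf$shaped[-drop]
    buf$seqs <- buf$seqs[-drop]
  }
  buf
}

#' Sample trajectories from a replay buffer with reward-proportional priority
#'
#' Draws without replacement; at each draw the selection probability of a
#' remaining entry is proportional to its reward (uniform if all remaining
#' rewards are zero). `k` at or above the buffer size returns the whole
#' buffer.
#'
#' @param buf a non-empty [replay_buffer()].
#' @param k number of draws.
#' @param seed sampling seed.
#' @return integer vector of selected entry indices (use with `buf$seqs`,
#'   `buf$shaped` etc.).
#' @export
buffer_sample <- function(buf, k, seed = 1L) {
  stopifnot(inherits(buf, "replay_buffer"))
  n <- length(buf$smiles)
  if (n == 0) stop("cannot sample from an empty buffer")
  if (k >= n) return(seq_len(n))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  picked <- integer(0)
  remaining <- seq_len(n)
  for (i in seq_len(k)) {
    w <- buf$reward[remaining]
    p <- if (sum(w) > 0) w / sum(w) else rep(1 / length(remaining), length(remaining))
    j <- remaining[.categorical_draw(p)]
    picked <- c(picked, j)
    remaining <- setdiff(remaining, j)
  }
  picked
}

# one categorical draw by inverse cdf from R's uniform stream
.categorical_draw <- function(p) {
  u <- stats::runif(1)
  min(findInterval(u, cumsum(p), left.open = TRUE) + 1L, length(p))
}
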