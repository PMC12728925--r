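# Sphere-exclusion diversity: the fraction of a fixed-size random sample
# of a run's molecules that survives greedy sphere exclusion at a Tanimoto
# threshold — a chemical-space coverage proxy.

#' Sphere-exclusion diversity (SEDiv)
#'
#' A seeded random sample of `sample_size` molecules (all of them when
#' fewer are available) is scanned greedily in sample order; a molecule
#' founds a new sphere center iff its Tanimoto similarity to every
#' existing center is strictly below `threshold` (a tie falls inside the
#' sphere). The result is `centers / n_sampled`, in `(0, 1]`.
#'
#' @param mols character vector of valid SMILES (typically the distinct
#'   canonical molecules of a run).
#' @param threshold Tanimoto sphere radius (default 0.65).
#' @param sample_size sample size the count is normalized by (default 1000).
#' @param seed sampling seed.
#' @return diversity in `(0, 1]`.
#' @export
sphere_exclusion_diversity <- function(mols, threshold = 0.65,
                                       sample_size = 1000L, seed = 1L) {
  if (length(mols) == 0) stop("sphere_exclusion_diversity() needs molecules")
  mols <- as.character(mols)
  if (length(mols) > sample_size) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed %% 2147483647))
    mols <- mols[sample.int(length(mols), sample_size)]
  }
  fps <- ecfp4(mols)
  n <- length(fps)
  # all pairwise Tanimoto similarities in one crossproduct of the bit matrix
  nbits <- attr(fps[[1]], "nbits")
  X <- matrix(0, nbits, n)
  for (i in seq_len(n)) X[fps[[i]], i] <- 1
  inter <- crossprod(X)
  card <- colSums(X)
  uni <- outer(card, card, `+`) - inter
  sims <- ifelse(uni > 0, inter / uni, 0)
  centers <- integer(0)
  for (i in seq_len(n)) {
    if (length(centers) == 0 || max(sims[i, centers]) < threshold) {
      centers <- c(centers, i)
    }
  }
  length(centers) / n
}
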