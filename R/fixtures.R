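# Seeded synthetic data: a toy SMILES corpus from a validity-preserving
# grammar, and multi-target rediscovery tasks with controlled inter-target
# dissimilarity. These stand in for a drug-like pretraining set and
# curated drug-candidate target sets at desk scale.

#' Generate a toy SMILES corpus from a valid-fragment grammar
#'
#' Molecules are composed of chains of heavy atoms with optional branches
#' (carbon attachment points only, keeping valences safe) and optional
#' benzene / cyclohexane ring units, so every emitted string is valid by
#' construction (asserted through the canonicalizer). Emission is
#' seeded-deterministic and strings are pairwise distinct.
#'
#' @param size number of distinct molecules.
#' @param max_heavy_atoms upper bound on heavy atoms per molecule.
#' @param atoms allowed chain atoms.
#' @param p_branch probability of opening a branch after a chain carbon.
#' @param p_ring probability that a unit is a ring instead of an atom.
#' @param seed generation seed.
#' @return character vector of `size` distinct valid SMILES.
#' @export
generate_toy_corpus <- function(size, max_heavy_atoms = 12L,
                                atoms = c("C", "N", "O"), p_branch = 0.3,
                                p_ring = 0.2, seed = 1L) {
  stopifnot(size >= 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  out <- character(0)
  attempts <- 0L
  max_attempts <- 200L * size
  while (length(out) < size) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("grammar space too small for ", size, " distinct molecules; ",
           "increase max_heavy_atoms or relax the grammar")
    }
    s <- .gen_molecule(max_heavy_atoms, atoms, p_branch, p_ring)
    if (!exists(s, envir = seen, inherits = FALSE)) {
      assign(s, TRUE, envir = seen)
      out <- c(out, s)
    }
  }
  bad <- !smiles_is_valid(out)
  if (any(bad)) {
    stop("internal error: grammar emitted invalid SMILES: ",
         paste(utils::head(out[bad], 3), collapse = ", "))
  }
  out
}

# one molecule from the grammar; budget counts heavy atoms
.gen_molecule <- function(max_heavy, atoms, p_branch, p_ring) {
  budget <- sample(3:max_heavy, 1)
  parts <- character(0)
  while (budget > 0) {
    if (budget >= 6 && stats::runif(1) < p_ring) {
      ring <- if (stats::runif(1) < 0.5) "c1ccccc1" else "C1CCCCC1"
      parts <- c(parts, ring)
      budget <- budget - 6L
    } else {
      a <- sample(atoms, 1)
      parts <- c(parts, a)
      budget <- budget - 1L
      # branches hang off carbons only (N/O valences stay safe in-chain)
      if (a == "C" && budget >= 1 && stats::runif(1) < p_branch) {
        blen <- sample(seq_len(min(3L, budget)), 1)
        branch <- paste(sample(atoms, blen, replace = TRUE), collapse = "")
        parts <- c(parts, paste0("(", branch, ")"))
        budget <- budget - blen
      }
    }
  }
  paste(parts, collapse = "")
}

#' Generate a toy multi-target rediscovery task
#'
#' Picks `n_targets` molecules from the corpus whose pairwise ECFP4
#' Tanimoto similarities are all at or below `max_pairwise_sim`,
#' emulating structurally dissimilar molecules that share one reward
#' landscape. For a string-edit oracle the same ceiling is additionally
#' enforced on pairwise normalized Levenshtein similarity of the
#' canonical SMILES, so the targets form distinct modes in the metric
#' the reward is actually computed in. Targets are drawn from the upper
#' length tercile of the corpus and matched in length (within 20% of the
#' first target), keeping chance rediscovery rare and the targets
#' comparably difficult. They are removed from the returned pretraining
#' split — the task is rediscovery, not recall.
#'
#' @param corpus a [generate_toy_corpus()] corpus.
#' @param n_targets number of targets (benchmark tasks use 2-4).
#' @param max_pairwise_sim inter-target similarity ceiling (default 0.3).
#' @param oracle_kind `"levenshtein"` or `"tanimoto"`.
#' @param seed selection seed.
#' @param name task label (default derived from `n_targets`).
#' @return list with `task` (a [task_spec()]) and `corpus` (the input
#'   corpus minus the targets).
#' @export
generate_toy_task <- function(corpus, n_targets = 2L, max_pairwise_sim = 0.3,
                              oracle_kind = "levenshtein", seed = 1L,
                              name = NULL) {
  stopifnot(n_targets >= 1, length(corpus) > n_targets)
  old <- .save_rng(); on.exit(.restore_rng(old))
  canon <- validate_and_canonicalize(corpus)
  sizes <- nchar(canon)
  pool0 <- which(sizes >= stats::quantile(sizes, 2 / 3))
  chosen <- integer(0)
  # greedy selection seeded from a different shuffle each restart: the
  # first pick anchors the length band, and some anchors are infeasible
  for (restart in seq_len(25L)) {
    if (restart == 1L) set.seed(as.integer(seed %% 2147483647))
    else set.seed(.derive_seed(seed, restart, stream = 6L))
    pool <- pool0[sample.int(length(pool0))]
    chosen <- integer(0)
    chosen_fps <- list()
    for (i in pool) {
      if (canon[i] %in% canon[chosen]) next
      if (length(chosen) > 0) {
        ref <- sizes[chosen[1]]
        if (abs(sizes[i] - ref) > 0.2 * ref) next
        if (oracle_kind == "levenshtein") {
          lev <- .lev_sim_cross(canon[i], canon[chosen])
          if (any(lev > max_pairwise_sim)) next
        }
      }
      fp <- ecfp4(canon[i])[[1]]
      if (all(vapply(chosen_fps, tanimoto, numeric(1), b = fp) <= max_pairwise_sim)) {
        chosen <- c(chosen, i)
        chosen_fps <- c(chosen_fps, list(fp))
        if (length(chosen) == n_targets) break
      }
    }
    if (length(chosen) == n_targets) break
  }
  if (length(chosen) < n_targets) {
    stop("could not find ", n_targets, " targets with pairwise similarity <= ",
         max_pairwise_sim, "; loosen the cutoff or enlarge the corpus")
  }
  if (is.null(name)) name <- paste0("toy-", n_targets, "tgt-s", seed)
  task <- task_spec(name, corpus[chosen], oracle_kind)
  keep <- !(canon %in% canon[chosen])
  list(task = task, corpus = corpus[keep])
}

#' A four-task toy benchmark suite
#'
#' Tasks with 2, 3, 3 and 4 targets drawn from one corpus (mirroring a
#' multi-target rediscovery suite over drug-candidate sets of those
#' sizes), all targets excluded from the returned pretraining split.
#'
#' @param corpus a [generate_toy_corpus()] corpus.
#' @param oracle_kind `"levenshtein"` or `"tanimoto"`.
#' @param max_pairwise_sim inter-target Tanimoto ceiling.
#' @param seed selection seed.
#' @return list with `tasks` (list of 4 [task_spec()]s) and `corpus` (the
#'   pruned pretraining split).
#' @export
toy_benchmark_suite <- function(corpus, oracle_kind = "levenshtein",
                                max_pairwise_sim = 0.3, seed = 1L) {
  sizes <- c(2L, 3L, 3L, 4L)
  tasks <- vector("list", length(sizes))
  left <- corpus
  removed <- character(0)
  for (k in seq_along(sizes)) {
    tk <- generate_toy_task(left, sizes[k], max_pairwise_sim, oracle_kind,
                            seed = .derive_seed(seed, k, stream = 5L),
                            name = paste0("toy-task", k, "-", sizes[k], "tgt"))
    removed <- c(removed, setdiff(left, tk$corpus))
    left <- tk$corpus
    tasks[[k]] <- tk$task
  }
  list(tasks = tasks, corpus = left)
}
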