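# Multi-target rediscovery tasks: the oracle returns the similarity to the
# nearest target molecule; benchmark performance is the product over
# targets of the run-wide maximum similarity achieved.

#' Define a rediscovery task
#'
#' A task names a set of structurally distinct target molecules and a
#' similarity oracle. The oracle reward of a molecule is its similarity to
#' the nearest target; the task is solved when every target has been
#' rediscovered exactly.
#'
#' @param name task label.
#' @param targets character vector of target SMILES (canonicalized here;
#'   must be valid and pairwise distinct). Benchmark tasks use 2-4 targets;
#'   a single target is allowed for per-target calibration runs.
#' @param oracle_kind `"levenshtein"` (normalized string-edit similarity on
#'   canonical SMILES), `"tanimoto"` (ECFP4/Tanimoto), or `"external"` (a
#'   user oracle).
#' @param threshold optional hit threshold in `[0, 1]`.
#' @param oracle_fn for `oracle_kind = "external"`: a function taking a
#'   character vector of canonical SMILES and returning rewards in
#'   `[0, 1]` (one per molecule).
#' @return a `task_spec` object.
#' @export
task_spec <- function(name, targets, oracle_kind = c("levenshtein", "tanimoto",
                                                     "external"),
                      threshold = NULL, oracle_fn = NULL) {
  oracle_kind <- match.arg(oracle_kind)
  targets <- as.character(targets)
  if (length(targets) < 1) stop("field 'targets': at least one target required")
  canon <- validate_and_canonicalize(targets)
  if (anyNA(canon)) {
    stop("field 'targets': invalid SMILES: ",
         paste(targets[is.na(canon)], collapse = ", "))
  }
  if (anyDuplicated(canon)) {
    stop("field 'targets': duplicate target molecules: ",
         paste(canon[duplicated(canon)], collapse = ", "))
  }
  if (!is.null(threshold) && (threshold < 0 || threshold > 1)) {
    stop("field 'threshold': must lie in [0, 1]")
  }
  if (oracle_kind == "external" && !is.function(oracle_fn)) {
    stop("field 'oracle': external oracle requires an oracle_fn callback")
  }
  t <- list(name = as.character(name), targets = canon,
            oracle_kind = oracle_kind, threshold = threshold,
            oracle_fn = oracle_fn)
  if (oracle_kind == "tanimoto") t$target_fps <- ecfp4(canon)
  class(t) <- "task_spec"
  t
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", x$name, ": ", length(x$targets), " target(s), ",
      x$oracle_kind, " oracle\n", sep = "")
  invisible(x)
}

#' Load a task from a YAML file
#'
#' Schema: `name`, `oracle` (one of levenshtein/tanimoto/external),
#' `targets` (list of SMILES), optional `threshold`.
#'
#' @param path YAML file path.
#' @param oracle_fn callback for external-oracle tasks.
#' @return a [task_spec()].
#' @export
load_task <- function(path, oracle_fn = NULL) {
  if (!file.exists(path)) stop("task file not found: ", path)
  y <- yaml::read_yaml(path)
  for (field in c("name", "oracle", "targets")) {
    if (is.null(y[[field]])) stop("task file missing field '", field, "'")
  }
  if (!y$oracle %in% c("levenshtein", "tanimoto", "external")) {
    stop("field 'oracle': unknown oracle kind '", y$oracle, "'")
  }
  targets <- unlist(y$targets)
  if (length(targets) < 2) stop("field 'targets': benchmark tasks need >= 2 targets")
  task_spec(y$name, targets, y$oracle, threshold = y$threshold,
            oracle_fn = oracle_fn)
}

#' Write a task to a YAML file
#'
#' @param task a [task_spec()].
#' @param path output path.
#' @export
write_task <- function(task, path) {
  stopifnot(inherits(task, "task_spec"))
  y <- list(name = task$name, oracle = task$oracle_kind,
            targets = as.list(task$targets))
  if (!is.null(task$threshold)) y$threshold <- task$threshold
  yaml::write_yaml(y, path)
  invisible(path)
}

# similarity of canonical SMILES (NA = invalid -> 0) to every target;
# rows = molecules, cols = targets. Computed once per sample and reused by
# both the oracle reward and the score trace.
.task_similarities <- function(canonical, task) {
  k <- length(task$targets)
  n <- length(canonical)
  sims <- matrix(0, n, k)
  ok <- which(!is.na(canonical))
  if (length(ok) == 0) return(sims)
  if (task$oracle_kind == "levenshtein") {
    sims[ok, ] <- .lev_sim_cross(canonical[ok], task$targets)
  } else if (task$oracle_kind == "tanimoto") {
    fps <- ecfp4(canonical[ok])
    sims[ok, ] <- .tanimoto_cross(fps, task$target_fps)
  } else {
    r <- task$oracle_fn(canonical[ok])
    if (length(r) != length(ok)) stop("external oracle returned wrong length")
    # external oracles score molecules, not targets; the trace tracks
    # structural similarity to the targets for reporting
    fps <- ecfp4(canonical[ok])
    sims[ok, ] <- .tanimoto_cross(fps, ecfp4(task$targets))
    attr(sims, "external_reward") <- list(idx = ok, reward = r)
  }
  sims
}

#' Oracle reward of molecules on a task
#'
#' The similarity to the nearest target molecule,
#' `max_t sim(m, target_t)`; invalid SMILES score 0. For external oracles
#' the callback's score is returned directly.
#'
#' @param smiles character vector of SMILES (need not be canonical).
#' @param task a [task_spec()].
#' @return numeric rewards in `[0, 1]`.
#' @export
oracle_reward <- function(smiles, task) {
  stopifnot(inherits(task, "task_spec"))
  canonical <- validate_and_canonicalize(smiles)
  sims <- .task_similarities(canonical, task)
  ext <- attr(sims, "external_reward")
  if (!is.null(ext)) {
    out <- numeric(length(smiles))
    out[ext$idx] <- ext$reward
    return(out)
  }
  if (nrow(sims) == 0) return(numeric())
  apply(sims, 1, max)
}

# ---- budget and score trace ---------------------------------------------

#' Budget ledger
#'
#' Counts every sampled string — valid or not, duplicate or not — against
#' the molecule budget.
#'
#' @param budget positive number of allowed samples.
#' @return a `budget_ledger` list with `budget` and `consumed`.
#' @export
budget_ledger <- function(budget) {
  stopifnot(budget >= 1)
  structure(list(budget = as.integer(budget), consumed = 0L),
            class = "budget_ledger")
}

#' Per-target maximum-similarity trace
#'
#' @param n_targets number of targets tracked.
#' @return a `score_trace` with `per_target_max` (all zeros) and an empty
#'   `history`.
#' @export
score_trace <- function(n_targets) {
  structure(list(per_target_max = numeric(n_targets),
                 history = list()),
            class = "score_trace")
}

#' Record one sampled molecule against a ledger and trace
#'
#' Consumes one unit of budget (erroring when the budget is already
#' exhausted) and folds the molecule's per-target similarities into the
#' running maxima. Invalid molecules consume budget but leave the trace
#' unchanged.
#'
#' @param ledger a [budget_ledger()].
#' @param trace a [score_trace()].
#' @param smiles one sampled SMILES string.
#' @param task the [task_spec()].
#' @return list with the updated `ledger` and `trace`.
#' @export
record_sample <- function(ledger, trace, smiles, task) {
  stopifnot(inherits(ledger, "budget_ledger"), inherits(trace, "score_trace"))
  if (ledger$consumed >= ledger$budget) {
    stop("budget exhausted: ", ledger$budget, " samples already recorded")
  }
  ledger$consumed <- ledger$consumed + 1L
  canonical <- validate_and_canonicalize(smiles)
  sims <- .task_similarities(canonical, task)
  trace$per_target_max <- pmax(trace$per_target_max, sims[1, ])
  list(ledger = ledger, trace = trace)
}

#' Task score: product of per-target maxima
#'
#' @param trace a [score_trace()] or a numeric vector of per-target maxima.
#' @return the product, in `[0, 1]`; 1 iff every target was rediscovered
#'   exactly.
#' @export
task_score <- function(trace) {
  m <- if (inherits(trace, "score_trace")) trace$per_target_max else trace
  if (length(m) < 1) stop("score trace has no targets")
  prod(m)
}

#' Benchmark sum over tasks
#'
#' @param task_scores numeric vector, one score per task.
#' @return their sum (bounded above by the number of tasks).
#' @export
benchmark_sum <- function(task_scores) {
  sum(task_scores)
}
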