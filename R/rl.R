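# The REINFORCE optimization loop. One step samples a batch from the
# agent policy, scores it with the task oracle (plus optional novelty
# bonus and diversity filter), reshapes rewards against the frozen prior,
# augments the batch with prioritized replay, and takes one Adam step on
# the reward-weighted log-likelihood. The step is split into
# collect / shape / update phases so population strategies can interleave
# cross-agent computations; the single-agent runner composes the phases
# directly, which makes a 1-agent independent population bit-identical to
# a plain run.

#' RL engine configuration
#'
#' @param batch_size molecules sampled (and counted against the budget)
#'   per step.
#' @param shaping a [shaping_config()] (prior coefficient and exponent).
#' @param lr Adam learning rate for policy updates.
#' @param buffer_capacity replay buffer size.
#' @param replay_k replayed trajectories appended per step (0 disables
#'   replay).
#' @param use_rnd add a random-network-distillation novelty bonus to the
#'   raw reward before reshaping.
#' @param rnd_bonus_scale bonus multiplier when `use_rnd` is on.
#' @param use_df zero the reward of repeated canonical SMILES.
#' @param canonicalize score canonical SMILES (the default). Turning this
#'   off treats generated strings as opaque identifiers — used for
#'   non-chemical diagnostic policies such as bandit sanity checks.
#' @param reward_fn optional override oracle: a function from generated
#'   strings to rewards in `[0, 1]`, replacing the task oracle.
#' @return an `rl_config` list.
#' @export
rl_config <- function(batch_size = 64L, shaping = shaping_config(),
                      lr = 1e-3, buffer_capacity = 100L, replay_k = 10L,
                      use_rnd = FALSE, rnd_bonus_scale = 0.1,
                      use_df = FALSE, canonicalize = TRUE,
                      reward_fn = NULL) {
  structure(list(batch_size = as.integer(batch_size), shaping = shaping,
                 lr = lr, buffer_capacity = as.integer(buffer_capacity),
                 replay_k = as.integer(replay_k), use_rnd = use_rnd,
                 rnd_bonus_scale = rnd_bonus_scale, use_df = use_df,
                 canonicalize = canonicalize, reward_fn = reward_fn),
            class = "rl_config")
}

# internal agent state for one policy being optimized on one task
.agent_new <- function(policy, task, budget, cfg, seed) {
  n_targets <- if (is.null(task)) 1L else length(task$targets)
  prior <- policy  # frozen copy of the starting (pretrained) policy
  list(policy = policy, prior = prior, opt = .adam_init(policy$params),
       buffer = replay_buffer(cfg$buffer_capacity),
       df = if (cfg$use_df) df_memory() else NULL,
       rnd = if (cfg$use_rnd) {
         rnd_state(bonus_scale = cfg$rnd_bonus_scale,
                   seed = .derive_seed(seed, 0L, stream = 9L))
       } else NULL,
       seed = seed, step = 0L,
       ledger = budget_ledger(budget),
       trace = score_trace(n_targets),
       rows = list())
}

# phase 1: sample, canonicalize, score, account budget, update trace.
.rl_collect <- function(agent, task, cfg) {
  remaining <- agent$ledger$budget - agent$ledger$consumed
  if (remaining <= 0) stop("budget exhausted")
  m <- min(cfg$batch_size, remaining)  # truncate the final batch
  samp <- sample_batch(agent$policy, m,
                       seed = .derive_seed(agent$seed, agent$step, stream = 0L))
  smiles <- samp$smiles
  canonical <- if (cfg$canonicalize) validate_and_canonicalize(smiles) else smiles
  valid <- !is.na(canonical)
  if (is.null(cfg$reward_fn)) {
    sims <- .task_similarities(canonical, task)
    ext <- attr(sims, "external_reward")
    if (is.null(ext)) {
      reward_raw <- if (nrow(sims)) apply(sims, 1, max) else numeric()
    } else {
      reward_raw <- numeric(m)
      reward_raw[ext$idx] <- ext$reward
    }
  } else {
    reward_raw <- cfg$reward_fn(smiles)
    sims <- matrix(reward_raw, ncol = 1)
  }
  agent$ledger$consumed <- agent$ledger$consumed + m
  if (nrow(sims)) {
    agent$trace$per_target_max <- pmax(agent$trace$per_target_max,
                                       apply(sims, 2, max))
  }
  agent$trace$history[[length(agent$trace$history) + 1L]] <-
    agent$trace$per_target_max
  r_eff <- reward_raw
  if (!is.null(agent$df)) {
    r_eff <- apply_diversity_filter(agent$df, canonical, r_eff)
  }
  if (!is.null(agent$rnd) && any(valid)) {
    fps <- ecfp4(canonical[valid])
    r_eff[valid] <- r_eff[valid] + rnd_bonus(agent$rnd, fps)
    agent$rnd <- rnd_update(agent$rnd, fps)
  }
  batch <- list(seqs = samp$seqs, smiles = smiles, canonical = canonical,
                valid = valid, logp = samp$logp, sims = sims,
                reward_raw = reward_raw, r_eff = r_eff, m = m)
  list(agent = agent, batch = batch)
}

# phase 2: prior log-probabilities and reward reshaping.
.rl_shape <- function(agent, batch, cfg) {
  batch$log_prior <- sequence_log_prob(agent$prior, batch$seqs)
  batch$shaped <- reshape_reward(batch$r_eff, batch$log_prior, cfg$shaping)
  batch
}

# phase 3: replay augmentation, gradient step, buffer insertion, logging.
# `weights` defaults to the shaped rewards; population strategies may pass
# adjusted returns. `buffer` may be a shared buffer; `insert_ok` filters
# insertions (purge). Returns agent and the possibly-shared buffer.
.rl_update <- function(agent, batch, cfg, weights = batch$shaped,
                       buffer = agent$buffer, insert_ok = NULL,
                       extra_grads = NULL, extra_scale = 0) {
  seqs <- batch$seqs
  w <- weights
  if (cfg$replay_k > 0 && length(buffer$smiles) > 0) {
    idx <- buffer_sample(buffer, cfg$replay_k,
                         seed = .derive_seed(agent$seed, agent$step, stream = 1L))
    # replayed trajectories are re-scored under the current policy inside
    # the gradient call (off-policy correction by recomputation)
    seqs <- c(seqs, buffer$seqs[idx])
    w <- c(w, buffer$shaped[idx])
  }
  res <- .policy_update(agent$policy, agent$opt, seqs, w, cfg$lr,
                        extra_grads = extra_grads, extra_scale = extra_scale)
  agent$policy <- res$policy
  agent$opt <- res$opt
  ins <- which(batch$valid & batch$reward_raw > 0)
  for (i in ins) {
    if (!is.null(insert_ok) && !insert_ok(batch$canonical[i])) next
    buffer <- buffer_insert(buffer, batch$canonical[i], batch$reward_raw[i],
                            batch$seqs[[i]], shaped = batch$shaped[i])
  }
  agent$step <- agent$step + 1L
  row <- data.frame(iteration = agent$step, smiles = batch$smiles,
                    canonical = ifelse(batch$valid, batch$canonical, NA),
                    valid = batch$valid, reward_raw = batch$reward_raw,
                    reward_shaped = batch$shaped,
                    stringsAsFactors = FALSE)
  sims <- batch$sims
  colnames(sims) <- paste0("sim_", seq_len(ncol(sims)))
  agent$rows[[length(agent$rows) + 1L]] <- cbind(row, sims)
  list(agent = agent, buffer = buffer)
}

#' One REINFORCE step
#'
#' Sample a batch (truncated to the remaining budget), score it, reshape
#' rewards, augment with replay and take one gradient update. With
#' `sigma = 0`, `alpha = 1`, an empty buffer and no exploration mechanism
#' this is one step of vanilla REINFORCE.
#'
#' @param agent an agent state from [rl_agent()].
#' @param task the [task_spec()] (or `NULL` when `cfg$reward_fn` is used).
#' @param cfg an [rl_config()].
#' @return the updated agent state.
#' @export
rl_step <- function(agent, task, cfg = rl_config()) {
  col <- .rl_collect(agent, task, cfg)
  batch <- .rl_shape(col$agent, col$batch, cfg)
  upd <- .rl_update(col$agent, batch, cfg)
  agent <- upd$agent
  agent$buffer <- upd$buffer
  agent
}

#' Create an agent state for step-wise optimization
#'
#' Freezes the supplied policy as the prior, initializes the optimizer,
#' replay buffer, budget ledger and score trace.
#'
#' @param policy the pretrained `clm_policy` to fine-tune.
#' @param task a [task_spec()] or `NULL`.
#' @param budget total molecule budget.
#' @param cfg an [rl_config()].
#' @param seed agent seed; all step-level randomness derives from it.
#' @return an agent state (a list; pass to [rl_step()]).
#' @export
rl_agent <- function(policy, task, budget, cfg = rl_config(), seed = 1L) {
  .agent_new(policy, task, budget, cfg, seed)
}

# assemble the public run record from a finished agent
.run_record <- function(agent, task, cfg) {
  samples <- do.call(rbind, agent$rows)
  rec <- list(samples = samples,
              per_target_max = agent$trace$per_target_max,
              history = agent$trace$history,
              score = task_score(agent$trace$per_target_max),
              consumed = agent$ledger$consumed,
              budget = agent$ledger$budget,
              buffer = agent$buffer,
              task = if (!is.null(task)) task$name else NA_character_,
              policy = agent$policy)
  class(rec) <- "run_record"
  rec
}

#' @export
print.run_record <- function(x, ...) {
  cat("<run_record> task ", x$task, ": ", x$consumed, "/", x$budget,
      " samples, score ", signif(x$score, 4), "\n", sep = "")
  invisible(x)
}

#' Distinct valid molecules generated during a run
#'
#' @param record a `run_record` (or its `samples` data frame).
#' @return character vector of unique canonical SMILES.
#' @export
run_molecules <- function(record) {
  s <- if (inherits(record, "run_record")) record$samples else record
  unique(s$canonical[s$valid])
}

#' Run a single RL agent to budget exhaustion
#'
#' Repeats [rl_step()] until the molecule budget is consumed (every sampled
#' string counts, valid or not). Fully deterministic for a fixed seed.
#'
#' @param policy the pretrained `clm_policy`.
#' @param task a [task_spec()], or `NULL` with `cfg$reward_fn`.
#' @param budget total molecule budget (full-scale default 10,000; pass
#'   smaller values for desk-scale work).
#' @param cfg an [rl_config()].
#' @param seed run seed.
#' @return a `run_record`: per-sample data frame, per-target maxima and
#'   their history, the final product-of-max `score`, and the fine-tuned
#'   policy.
#' @export
rl_run <- function(policy, task, budget = 10000L, cfg = rl_config(),
                   seed = 1L) {
  if (is.null(cfg$reward_fn)) stopifnot(inherits(task, "task_spec"))
  agent <- .agent_new(policy, task, budget, cfg, seed)
  while (agent$ledger$consumed < agent$ledger$budget) {
    agent <- rl_step(agent, task, cfg)
  }
  .run_record(agent, task, cfg)
}
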