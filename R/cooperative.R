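# Population strategies: N agents optimize the same task, either fully
# independently or coupled through their replay buffers, reward bonuses or
# auxiliary specialization/diversity losses. Every coupling mechanism is
# scaled by an explicit coefficient (noise_sigma for parameter noise,
# bonus_b for reward bonuses, lambda for everything else, including buffer
# topology), so any strategy with all coefficients zeroed degenerates
# exactly to independent agents — a useful reduction contract for testing
# and ablation.

.STRATEGIES <- c("independent", "noise", "shared", "shared_bonus", "purge",
                 "rnd", "ent_s", "ce_s", "diff_s", "diff_n", "dvd", "popnorm")

#' Population strategy configuration
#'
#' @param lambda weight of auxiliary losses (`ent_s`, `ce_s`, `diff_s`,
#'   `diff_n`, `dvd`), and the generic gate for structural couplings:
#'   buffer sharing (`shared`, `shared_bonus`), buffer purging (`purge`)
#'   and return normalization (`popnorm`) are active iff `lambda != 0`.
#' @param noise_sigma standard deviation of the Gaussian parameter noise
#'   applied per agent at initialization under the `noise` strategy.
#' @param bonus_b reward bonus for novel states (`shared_bonus`), and the
#'   bonus scale for the `rnd` strategy.
#' @param probe_size number of frozen probe sequences defining the
#'   behavior embedding (`dvd`).
#' @param kernel_bandwidth RBF bandwidth for the `dvd` kernel; `NULL` uses
#'   the median pairwise embedding distance.
#' @param dvd_floor lower floor on the log-determinant diversity score.
#' @return a `coop_config` list.
#' @export
coop_config <- function(lambda = 0.1, noise_sigma = 0.01, bonus_b = 0.1,
                        probe_size = 32L, kernel_bandwidth = NULL,
                        dvd_floor = -30) {
  structure(list(lambda = lambda, noise_sigma = noise_sigma,
                 bonus_b = bonus_b, probe_size = as.integer(probe_size),
                 kernel_bandwidth = kernel_bandwidth, dvd_floor = dvd_floor),
            class = "coop_config")
}

#' Initialize a population of agents
#'
#' Copies the base policy `n` times. The `noise` strategy perturbs every
#' parameter of each copy with i.i.d. Gaussian noise of standard deviation
#' `noise_sigma` (seeded per agent); all other strategies copy exactly.
#' For `dvd`, a frozen probe set is sampled from the base policy.
#'
#' @param base a pretrained `clm_policy`.
#' @param n number of agents (>= 1).
#' @param strategy one of `"independent"`, `"noise"`, `"shared"`,
#'   `"shared_bonus"`, `"purge"`, `"rnd"`, `"ent_s"`, `"ce_s"`, `"diff_s"`,
#'   `"diff_n"`, `"dvd"`, `"popnorm"`.
#' @param cfg a [coop_config()].
#' @param seed population seed.
#' @return a `population_state`.
#' @export
init_population <- function(base, n, strategy = "independent",
                            cfg = coop_config(), seed = 1L) {
  stopifnot(inherits(base, "clm_policy"), n >= 1)
  if (!strategy %in% .STRATEGIES) {
    stop("unknown strategy '", strategy, "'; valid: ",
         paste(.STRATEGIES, collapse = ", "))
  }
  policies <- vector("list", n)
  for (i in seq_len(n)) {
    p <- base
    if (strategy == "noise" && cfg$noise_sigma > 0) {
      old <- .save_rng()
      set.seed(.derive_seed(seed, i, stream = 2L))
      p$params <- .perturb(p$params, cfg$noise_sigma)
      .restore_rng(old)
    }
    policies[[i]] <- p
  }
  probes <- NULL
  if (strategy == "dvd") {
    probes <- sample_batch(base, cfg$probe_size,
                           seed = .derive_seed(seed, 0L, stream = 3L))$seqs
  }
  structure(list(policies = policies, n = n, strategy = strategy,
                 cfg = cfg, probes = probes, seed = seed),
            class = "population_state")
}

.perturb <- function(x, sigma) {
  if (is.list(x)) return(lapply(x, .perturb, sigma = sigma))
  x + stats::rnorm(length(x), 0, sigma)
}

#' @export
print.population_state <- function(x, ...) {
  cat("<population_state> ", x$n, " agents, strategy ", x$strategy, "\n",
      sep = "")
  invisible(x)
}

#' Population-mean return normalization
#'
#' Subtracts the population-wide mean return of the iteration from every
#' agent's per-state returns; the adjusted returns average to zero across
#' the population.
#'
#' @param returns_by_agent list of numeric return vectors, one per agent.
#' @return list of adjusted return vectors of the same shape.
#' @export
popnorm_adjust <- function(returns_by_agent) {
  all <- unlist(returns_by_agent)
  if (length(all) == 0) return(returns_by_agent)
  mu <- mean(all)
  lapply(returns_by_agent, function(r) r - mu)
}

#' Reward bonus for states absent from a shared buffer
#'
#' @param buffer the shared [replay_buffer()].
#' @param canonical character vector of canonical SMILES (`NA` for invalid
#'   molecules, which get no bonus).
#' @param bonus_b bonus value.
#' @return numeric vector: `bonus_b` where novel, else 0.
#' @export
shared_bonus <- function(buffer, canonical, bonus_b) {
  ifelse(!is.na(canonical) & !(canonical %in% buffer$smiles), bonus_b, 0)
}

# ---- specialization losses ----------------------------------------------
# "Policy uncertainty" of a state is its per-token-averaged NLL. The
# per-state confidence over agents is the softmax of total sequence
# log-probabilities.

#' Auxiliary specialization losses over population states
#'
#' Given the matrix of sequence log-probabilities of the iteration's
#' pooled states under every agent, computes the auxiliary loss for one
#' agent and the per-state coefficients `d aux / d log p_i(s)` needed for
#' its gradient:
#'
#' * `ent_s` — mean entropy of the per-state agent-confidence (softmax over
#'   agents of sequence log-probability); minimizing encourages each state
#'   to be claimed by one agent.
#' * `ce_s` — mean cross-entropy of that confidence against the one-hot of
#'   the state's originating agent.
#' * `diff_s` — agent's mean per-token NLL on its own states minus on the
#'   rest of the population's states.
#' * `diff_n` — negative mean log-probability gap between the agent and the
#'   other agents on the agent's own on-policy states.
#'
#' With a single agent every loss is identically zero.
#'
#' @param kind one of `"ent_s"`, `"ce_s"`, `"diff_s"`, `"diff_n"`.
#' @param logp matrix of sequence log-probabilities, states x agents.
#' @param lengths per-state token counts (per-token NLL normalization).
#' @param origin integer vector: which agent generated each state.
#' @param agent_i the agent the loss and coefficients are computed for.
#' @return list with `value` (scalar loss) and `coef` (per-state gradient
#'   coefficients for agent `agent_i`).
#' @export
specialization_loss <- function(kind, logp, lengths, origin, agent_i) {
  kind <- match.arg(kind, c("ent_s", "ce_s", "diff_s", "diff_n"))
  n_states <- nrow(logp)
  N <- ncol(logp)
  if (N < 2) return(list(value = 0, coef = numeric(n_states)))
  coef <- numeric(n_states)
  if (kind %in% c("ent_s", "ce_s")) {
    # per-state softmax over agents, numerically stabilized
    z <- logp - apply(logp, 1, max)
    conf <- exp(z) / rowSums(exp(z))
    if (kind == "ent_s") {
      lc <- log(pmax(conf, 1e-300))
      ent <- -rowSums(conf * lc)
      value <- mean(ent)
      coef <- -conf[, agent_i] * (lc[, agent_i] + ent) / n_states
    } else {
      one_hot <- as.numeric(origin == agent_i)
      value <- mean(-log(pmax(conf[cbind(seq_len(n_states), origin)], 1e-300)))
      coef <- (conf[, agent_i] - one_hot) / n_states
    }
  } else if (kind == "diff_s") {
    own <- origin == agent_i
    n_own <- sum(own); n_oth <- sum(!own)
    u <- -logp[, agent_i] / lengths          # per-token NLL = uncertainty
    value <- (if (n_own) mean(u[own]) else 0) -
             (if (n_oth) mean(u[!own]) else 0)
    if (n_own) coef[own] <- -1 / (lengths[own] * n_own)
    if (n_oth) coef[!own] <- 1 / (lengths[!own] * n_oth)
  } else {  # diff_n: maximize log-prob gap on own on-policy states
    own <- origin == agent_i
    n_own <- sum(own)
    if (n_own) {
      gaps <- sapply(setdiff(seq_len(N), agent_i), function(j) {
        mean(logp[own, agent_i] - logp[own, j])
      })
      value <- -mean(gaps)
      coef[own] <- -1 / n_own
    } else {
      value <- 0
    }
  }
  list(value = value, coef = coef)
}

# ---- diversity via determinant ------------------------------------------

#' Behavior embedding of a policy
#'
#' The vector of sequence log-probabilities the policy assigns to a fixed
#' probe set; deterministic for a fixed policy.
#'
#' @param policy a `clm_policy`.
#' @param probes list of probe token sequences (frozen at population
#'   initialization).
#' @return numeric vector of length `length(probes)`.
#' @export
behavior_embedding <- function(policy, probes) {
  sequence_log_prob(policy, probes)
}

.dvd_kernel <- function(emb, bandwidth = NULL) {
  d2 <- as.matrix(stats::dist(emb))^2
  if (is.null(bandwidth)) {
    pd <- sqrt(d2[upper.tri(d2)])
    bandwidth <- stats::median(pd)
    if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1
  }
  list(K = exp(-d2 / (2 * bandwidth^2)), bandwidth = bandwidth)
}

#' Population diversity score via kernel determinant
#'
#' Log-determinant of the RBF kernel matrix of the agents' behavior
#' embeddings (bandwidth: median pairwise distance unless given), floored
#' at `floor` to keep losses finite when embeddings coincide. Invariant
#' under permutation of the agents.
#'
#' @param embeddings numeric matrix, agents x probe dimensions.
#' @param bandwidth RBF bandwidth (`NULL` for the median heuristic).
#' @param floor lower floor on the returned log-determinant.
#' @return scalar diversity score (higher = more behaviorally diverse).
#' @export
dvd_score <- function(embeddings, bandwidth = NULL, floor = -30) {
  stopifnot(is.matrix(embeddings), nrow(embeddings) >= 2)
  kk <- .dvd_kernel(embeddings, bandwidth)
  K <- kk$K
  ld <- determinant(K, logarithm = TRUE)
  val <- as.numeric(ld$modulus)
  if (ld$sign <= 0 || !is.finite(val)) val <- floor
  max(val, floor)
}

# gradient of the (floored) log-det score w.r.t. each embedding row;
# zero at the floor. Returns agents x dim matrix.
.dvd_grad <- function(embeddings, bandwidth = NULL, floor = -30) {
  kk <- .dvd_kernel(embeddings, bandwidth)
  K <- kk$K
  bw2 <- kk$bandwidth^2
  ld <- determinant(K, logarithm = TRUE)
  g <- matrix(0, nrow(embeddings), ncol(embeddings))
  if (ld$sign <= 0 || as.numeric(ld$modulus) <= floor) return(g)
  Kinv <- tryCatch(solve(K), error = function(e) {
    solve(K + diag(1e-8, nrow(K)))  # jitter on numerically singular kernels
  })
  n <- nrow(embeddings)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      g[i, ] <- g[i, ] - 2 * Kinv[i, j] * K[i, j] *
        (embeddings[i, ] - embeddings[j, ]) / bw2
    }
  }
  g
}

#' Insert a trajectory under the purge buffer policy
#'
#' The molecule enters agent `i`'s buffer only if its canonical SMILES is
#' absent from every other agent's buffer, keeping the buffers pairwise
#' disjoint.
#'
#' @param buffers list of [replay_buffer()]s, one per agent.
#' @param agent_i inserting agent.
#' @param smiles canonical SMILES.
#' @param reward raw reward.
#' @param seq token sequence.
#' @param shaped shaped reward.
#' @return the updated list of buffers.
#' @export
purge_insert <- function(buffers, agent_i, smiles, reward, seq,
                         shaped = reward) {
  if (is.na(smiles)) return(buffers)
  others <- setdiff(seq_along(buffers), agent_i)
  for (j in others) {
    if (smiles %in% buffers[[j]]$smiles) return(buffers)
  }
  buffers[[agent_i]] <- buffer_insert(buffers[[agent_i]], smiles, reward,
                                      seq, shaped)
  buffers
}

# ---- the population runner ----------------------------------------------

#' Run a cooperative population on a task
#'
#' Agents take one batch each per cycle (round-robin, sequentially
#' deterministic given seeds), with the strategy's couplings applied:
#' buffer topology (`shared`, `shared_bonus`, `purge`), reward bonuses
#' (`shared_bonus`, `rnd`), return normalization (`popnorm`) and auxiliary
#' losses (`ent_s`, `ce_s`, `diff_s`, `diff_n`, `dvd`). The benchmark is
#' scored on the union of all agents' molecules. Agent `i` uses seed
#' `seed + i - 1`, so a 1-agent independent population reproduces
#' [rl_run()] with the same seed exactly.
#'
#' @param pop an [init_population()] state.
#' @param task the [task_spec()].
#' @param budget_per_agent molecule budget per agent.
#' @param cfg an [rl_config()].
#' @param seed run seed.
#' @return a `population_record`: per-agent `run_record`s plus union
#'   per-target maxima and union score.
#' @export
run_cooperative <- function(pop, task, budget_per_agent = 10000L,
                            cfg = rl_config(), seed = 1L) {
  stopifnot(inherits(pop, "population_state"))
  strategy <- pop$strategy
  ccfg <- pop$cfg
  N <- pop$n
  active <- ccfg$lambda != 0  # structural couplings gate
  shared_topology <- strategy %in% c("shared", "shared_bonus") && active
  purge_topology <- strategy == "purge" && active
  aux_kind <- if (strategy %in% c("ent_s", "ce_s", "diff_s", "diff_n")) strategy else NULL
  cfg_i <- cfg
  if (strategy == "rnd") {
    cfg_i$use_rnd <- TRUE
    cfg_i$rnd_bonus_scale <- ccfg$bonus_b
  }
  agents <- lapply(seq_len(N), function(i) {
    .agent_new(pop$policies[[i]], task, budget_per_agent, cfg_i,
               seed = seed + i - 1)
  })
  shared_buf <- if (shared_topology) replay_buffer(cfg$buffer_capacity) else NULL
  while (agents[[1]]$ledger$consumed < agents[[1]]$ledger$budget) {
    batches <- vector("list", N)
    for (i in seq_len(N)) {
      col <- .rl_collect(agents[[i]], task, cfg_i)
      agents[[i]] <- col$agent
      batches[[i]] <- col$batch
    }
    if (strategy == "shared_bonus" && active && ccfg$bonus_b != 0) {
      for (i in seq_len(N)) {
        batches[[i]]$r_eff <- batches[[i]]$r_eff +
          shared_bonus(shared_buf, batches[[i]]$canonical, ccfg$bonus_b)
      }
    }
    for (i in seq_len(N)) {
      batches[[i]] <- .rl_shape(agents[[i]], batches[[i]], cfg_i)
    }
    weights <- lapply(batches, `[[`, "shaped")
    if (strategy == "popnorm" && active) {
      weights <- popnorm_adjust(weights)
    }
    # auxiliary gradients over the cycle's pooled states
    aux <- vector("list", N)
    if (!is.null(aux_kind) && active && N >= 2) {
      pooled <- unlist(lapply(batches, `[[`, "seqs"), recursive = FALSE)
      lens <- lengths(pooled)
      origin <- rep(seq_len(N), vapply(batches, `[[`, integer(1), "m"))
      logp <- vapply(seq_len(N), function(j) {
        sequence_log_prob(agents[[j]]$policy, pooled)
      }, numeric(length(pooled)))
      pd <- .pad_sequences(pooled)
      for (i in seq_len(N)) {
        sl <- specialization_loss(aux_kind, logp, lens, origin, i)
        if (any(sl$coef != 0)) {
          # clm_grad computes d/dtheta of -(1/B) sum w*logp; choosing
          # w = -B*coef yields sum coef*dlogp, the aux gradient
          g <- .clm_grad_cpp(agents[[i]]$policy$params, pd$tokens, pd$lengths,
                             agents[[i]]$policy$vocab$bos,
                             -length(pooled) * sl$coef)
          aux[[i]] <- g$grads
        }
      }
    }
    if (strategy == "dvd" && active && N >= 2) {
      emb <- t(vapply(seq_len(N), function(j) {
        behavior_embedding(agents[[j]]$policy, pop$probes)
      }, numeric(length(pop$probes))))
      ge <- .dvd_grad(emb, ccfg$kernel_bandwidth, ccfg$dvd_floor)
      pd <- .pad_sequences(pop$probes)
      for (i in seq_len(N)) {
        coef <- -ge[i, ]  # loss adds -lambda * dvd, so descend its negative
        if (any(coef != 0)) {
          g <- .clm_grad_cpp(agents[[i]]$policy$params, pd$tokens, pd$lengths,
                             agents[[i]]$policy$vocab$bos,
                             -length(pop$probes) * coef)
          aux[[i]] <- g$grads
        }
      }
    }
    for (i in seq_len(N)) {
      if (purge_topology) {
        other_smiles <- unlist(lapply(agents[-i], function(a) a$buffer$smiles))
        ok <- function(s) !(s %in% other_smiles)
      } else ok <- NULL
      upd <- .rl_update(agents[[i]], batches[[i]], cfg_i,
                        weights = weights[[i]],
                        buffer = if (shared_topology) shared_buf else agents[[i]]$buffer,
                        insert_ok = ok,
                        extra_grads = aux[[i]],
                        extra_scale = ccfg$lambda)
      agents[[i]] <- upd$agent
      if (shared_topology) shared_buf <- upd$buffer
      else agents[[i]]$buffer <- upd$buffer
    }
  }
  if (shared_topology) {
    # the shared buffer is every agent's effective buffer
    for (i in seq_len(N)) agents[[i]]$buffer <- shared_buf
  }
  records <- lapply(agents, .run_record, task = task, cfg = cfg_i)
  union_max <- Reduce(pmax, lapply(records, `[[`, "per_target_max"))
  out <- list(agents = records, strategy = strategy,
              union_per_target_max = union_max,
              union_score = task_score(union_max),
              shared_buffer = shared_buf,
              consumed = sum(vapply(records, `[[`, numeric(1), "consumed")))
  class(out) <- "population_record"
  out
}

#' @export
print.population_record <- function(x, ...) {
  cat("<population_record> ", length(x$agents), " agents (", x$strategy,
      "), union score ", signif(x$union_score, 4), "\n", sep = "")
  invisible(x)
}
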