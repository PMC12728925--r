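# Test-time-training scaling protocols: scaling the number of independent
# agents at fixed per-agent budget, scaling the budget of a single agent
# (optionally with RND or a diversity filter), replicate aggregation and
# log-linear fits. Replicate seed = base_seed + 1000 * replicate; agent
# seed = replicate seed + agent index - 1 (nested, so the agent sets for
# increasing N are supersets).

#' Scale the number of independent agents on a task
#'
#' For every replicate, runs `max(agent_counts)` agents with nested seeds
#' and scores the union of the first `N` agents' molecules for each `N`
#' (per-target maxima over the union; the product is the task score).
#' With a non-independent strategy, each `N` is run as its own cooperative
#' population. SEDiv is computed over the union's distinct valid
#' molecules.
#'
#' @param policy the pretrained `clm_policy`.
#' @param task a [task_spec()].
#' @param agent_counts agent population sizes (default `c(1, 2, 4, 8)`;
#'   full-scale grids up to 128 remain expressible).
#' @param budget_per_agent molecule budget per agent.
#' @param replicates number of replicate runs (default 5).
#' @param base_seed experiment seed.
#' @param cfg an [rl_config()].
#' @param strategy population strategy (default `"independent"`).
#' @param coop_cfg a [coop_config()] for non-independent strategies.
#' @param sediv_size sample size for SEDiv (default 1000).
#' @return a `scaling_result`: `results` (one row per N x replicate),
#'   `summary` (mean and sd per N) and the log-linear `fit` on the means.
#' @export
scale_agents_experiment <- function(policy, task, agent_counts = c(1, 2, 4, 8),
                                    budget_per_agent = 1000L, replicates = 5L,
                                    base_seed = 1L, cfg = rl_config(),
                                    strategy = "independent",
                                    coop_cfg = coop_config(),
                                    sediv_size = 1000L) {
  stopifnot(all(agent_counts >= 1))
  agent_counts <- sort(unique(as.integer(agent_counts)))
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- base_seed + 1000L * r
    if (strategy == "independent") {
      n_max <- max(agent_counts)
      runs <- lapply(seq_len(n_max), function(i) {
        rl_run(policy, task, budget_per_agent, cfg, seed = rep_seed + i - 1)
      })
      for (N in agent_counts) {
        sub <- runs[seq_len(N)]
        union_max <- Reduce(pmax, lapply(sub, `[[`, "per_target_max"))
        mols <- unique(unlist(lapply(sub, run_molecules)))
        rows[[length(rows) + 1L]] <- data.frame(
          task = task$name, strategy = strategy, n_agents = N,
          budget_per_agent = budget_per_agent, replicate = r,
          score = task_score(union_max),
          sediv = sphere_exclusion_diversity(mols, sample_size = sediv_size,
                                             seed = rep_seed),
          stringsAsFactors = FALSE)
      }
    } else {
      for (N in agent_counts) {
        pop <- init_population(policy, N, strategy, coop_cfg,
                               seed = .derive_seed(rep_seed, N, stream = 4L))
        rec <- run_cooperative(pop, task, budget_per_agent, cfg,
                               seed = rep_seed)
        mols <- unique(unlist(lapply(rec$agents, run_molecules)))
        rows[[length(rows) + 1L]] <- data.frame(
          task = task$name, strategy = strategy, n_agents = N,
          budget_per_agent = budget_per_agent, replicate = r,
          score = rec$union_score,
          sediv = sphere_exclusion_diversity(mols, sample_size = sediv_size,
                                             seed = rep_seed),
          stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- aggregate_results(results, by = "n_agents")
  fit <- if (length(agent_counts) >= 3) {
    fit_log_linear(summary$n_agents, summary$score_mean)
  } else NULL
  structure(list(results = results, summary = summary, fit = fit),
            class = "scaling_result")
}

#' Scale the budget of a single agent on a task
#'
#' One agent per (budget, replicate), optionally with an RND exploration
#' bonus (`variant = "rnd"`) or a diversity filter (`variant = "df"`).
#'
#' @param policy the pretrained `clm_policy`.
#' @param task a [task_spec()].
#' @param budgets total molecule budgets to test.
#' @param variant `"plain"`, `"rnd"` or `"df"`.
#' @param replicates number of replicate runs.
#' @param base_seed experiment seed.
#' @param cfg an [rl_config()] (the variant toggles its exploration
#'   fields).
#' @param sediv_size SEDiv sample size.
#' @return a `scaling_result` over budgets.
#' @export
scale_budget_experiment <- function(policy, task,
                                    budgets = c(1000L, 2000L, 4000L),
                                    variant = c("plain", "rnd", "df"),
                                    replicates = 5L, base_seed = 1L,
                                    cfg = rl_config(), sediv_size = 1000L) {
  variant <- match.arg(variant)
  cfg$use_rnd <- variant == "rnd"
  cfg$use_df <- variant == "df"
  rows <- list()
  for (r in seq_len(replicates)) {
    rep_seed <- base_seed + 1000L * r
    for (B in budgets) {
      rec <- rl_run(policy, task, B, cfg, seed = rep_seed)
      rows[[length(rows) + 1L]] <- data.frame(
        task = task$name, strategy = paste0("single_", variant),
        budget = B, replicate = r, score = rec$score,
        sediv = sphere_exclusion_diversity(run_molecules(rec),
                                           sample_size = sediv_size,
                                           seed = rep_seed),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  structure(list(results = results,
                 summary = aggregate_results(results, by = "budget"),
                 fit = NULL),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("<scaling_result>\n")
  print(x$summary)
  if (!is.null(x$fit)) {
    cat(sprintf("log-linear fit: slope %.3f, intercept %.3f, R^2 %.3f\n",
                x$fit$slope, x$fit$intercept, x$fit$r_squared))
  }
  invisible(x)
}

#' Fit a log-linear scaling curve
#'
#' Least-squares fit of `score ~ log2(n)`; recovers synthetic log-linear
#' data exactly.
#'
#' @param n agent counts (or another scaling variable), >= 3 distinct
#'   values.
#' @param score mean scores per `n`.
#' @return list with `slope` (score per doubling), `intercept` (score at
#'   `n = 1`) and `r_squared`.
#' @export
fit_log_linear <- function(n, score) {
  if (length(unique(n)) < 3) stop("need at least 3 distinct scaling points")
  x <- log2(n)
  fit <- stats::lm(score ~ x)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((score - mean(score))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Aggregate replicate results
#'
#' Mean and sample standard deviation of `score` and `sediv` per group
#' (a single replicate reports sd 0).
#'
#' @param results a results data frame with `score`, `sediv` and the
#'   grouping column.
#' @param by grouping column name.
#' @return data frame with `*_mean` and `*_sd` columns per group.
#' @export
aggregate_results <- function(results, by = "n_agents") {
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  g <- results[[by]]
  out <- data.frame(unique(sort(g)))
  names(out) <- by
  for (col in intersect(c("score", "sediv"), names(results))) {
    mu <- tapply(results[[col]], g, mean)
    s <- tapply(results[[col]], g, sd0)
    out[[paste0(col, "_mean")]] <- as.numeric(mu[as.character(out[[by]])])
    out[[paste0(col, "_sd")]] <- as.numeric(s[as.character(out[[by]])])
  }
  out
}

#' Compare strategies against a baseline with one-tailed t-tests
#'
#' For each strategy, a one-tailed two-sample t-test of "strategy scores
#' greater than baseline scores" across replicates, Bonferroni-corrected
#' over the strategies tested.
#'
#' @param results data frame with `strategy`, `replicate` and `score`.
#' @param baseline the baseline strategy name.
#' @return data frame with per-strategy mean difference, t-statistic, raw
#'   and Bonferroni-adjusted one-tailed p-values.
#' @export
compare_strategies <- function(results, baseline = "independent") {
  base_scores <- results$score[results$strategy == baseline]
  if (length(base_scores) == 0) stop("no rows for baseline '", baseline, "'")
  others <- setdiff(unique(results$strategy), baseline)
  rows <- lapply(others, function(s) {
    x <- results$score[results$strategy == s]
    tt <- stats::t.test(x, base_scores, alternative = "greater")
    data.frame(strategy = s, mean_diff = mean(x) - mean(base_scores),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out
}
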