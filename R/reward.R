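# Prior-regularized reward reshaping and the REINFORCE objective.

#' Reward-shaping configuration
#'
#' @param sigma non-negative coefficient on the prior log-probability of
#'   the trajectory. Larger values pull the agent toward molecules the
#'   pretrained prior finds plausible.
#' @param alpha exponent (>= 1) steepening the reshaped reward landscape.
#' @return a `shaping_config` list.
#' @export
shaping_config <- function(sigma = 0.001, alpha = 3) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (alpha < 1) stop("alpha must be >= 1")
  structure(list(sigma = sigma, alpha = alpha), class = "shaping_config")
}

#' Reshape a raw reward with a prior-likelihood regularizer
#'
#' `clip(R + sigma * log_prior, 0)^alpha`: the raw reward is regularized by
#' the (non-positive) prior log-probability of the trajectory, clipped at
#' zero so the reshaped reward is always non-negative, then raised to
#' `alpha`. With `sigma = 0, alpha = 1` this is the identity on `R`; it is
#' non-decreasing in `R` for fixed `log_prior`.
#'
#' @param reward raw rewards in `[0, 1]` (a bonus may push slightly above 1).
#' @param log_prior non-positive log-probabilities under the prior policy.
#' @param config a [shaping_config()].
#' @return non-negative reshaped rewards.
#' @export
reshape_reward <- function(reward, log_prior, config = shaping_config()) {
  stopifnot(inherits(config, "shaping_config"))
  pmax(reward + config$sigma * log_prior, 0)^config$alpha
}

#' REINFORCE surrogate loss
#'
#' `-(1/n) * sum(reward * log_prob)`: the scalar whose gradient with
#' respect to the policy parameters is the (reward-weighted) REINFORCE
#' estimator. All-zero rewards give zero loss and zero gradient.
#'
#' @param rewards shaped rewards per trajectory.
#' @param log_probs trajectory log-probabilities under the current policy.
#' @return scalar loss.
#' @export
reinforce_loss <- function(rewards, log_probs) {
  if (length(rewards) == 0) stop("empty batch")
  if (any(!is.finite(log_probs))) stop("non-finite log-probability")
  -mean(rewards * log_probs)
}
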