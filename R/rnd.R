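# Random network distillation: a fixed random target network maps
# fingerprints to an embedding; a predictor network is trained toward the
# target, and its (running-normalized) squared prediction error is the
# novelty bonus. Frequently visited states become predictable and lose
# their bonus; unseen states keep a high one.

#' Create a random-network-distillation state
#'
#' Both networks are two-layer perceptrons `fingerprint -> hidden -> emb`.
#' The target network is frozen at initialization; only the predictor is
#' trained.
#'
#' @param nbits fingerprint length (input dimension).
#' @param emb_dim output embedding size.
#' @param hidden_dim hidden layer width.
#' @param bonus_scale multiplier on the normalized prediction error.
#' @param lr predictor Adam learning rate.
#' @param seed initialization seed.
#' @return an `rnd_state` object.
#' @export
rnd_state <- function(nbits = 2048L, emb_dim = 32L, hidden_dim = 64L,
                      bonus_scale = 0.1, lr = 1e-3, seed = 1L) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  mk <- function() {
    list(W1 = matrix(stats::rnorm(hidden_dim * nbits, 0, 1 / sqrt(nbits)),
                     hidden_dim, nbits),
         b1 = numeric(hidden_dim),
         W2 = matrix(stats::rnorm(emb_dim * hidden_dim, 0, 1 / sqrt(hidden_dim)),
                     emb_dim, hidden_dim),
         b2 = numeric(emb_dim))
  }
  target <- mk()
  predictor <- mk()
  structure(list(nbits = as.integer(nbits), emb_dim = as.integer(emb_dim),
                 hidden_dim = as.integer(hidden_dim),
                 bonus_scale = bonus_scale, lr = lr,
                 target = target, predictor = predictor,
                 opt = .adam_init(predictor),
                 err_mean = 0, err_var = 1, err_n = 0),
            class = "rnd_state")
}

# fingerprints (list of bit-position vectors) -> dense nbits x n matrix
.fp_dense <- function(fps, nbits) {
  x <- matrix(0, nbits, length(fps))
  for (i in seq_along(fps)) x[fps[[i]], i] <- 1
  x
}

.rnd_forward <- function(net, x) {
  h <- pmax(net$W1 %*% x + net$b1, 0)
  list(h = h, out = net$W2 %*% h + net$b2)
}

# per-column squared prediction error
.rnd_errors <- function(rnd, x) {
  t_out <- .rnd_forward(rnd$target, x)$out
  p_out <- .rnd_forward(rnd$predictor, x)$out
  colSums((t_out - p_out)^2)
}

#' Novelty bonus for fingerprints
#'
#' `bonus_scale` times the squared prediction error of the predictor
#' network against the frozen target, divided by the running standard
#' deviation of errors seen so far. Always non-negative.
#'
#' @param rnd an [rnd_state()].
#' @param fps list of fingerprints from [ecfp4()].
#' @return numeric vector of non-negative bonuses.
#' @export
rnd_bonus <- function(rnd, fps) {
  stopifnot(inherits(rnd, "rnd_state"))
  if (length(fps) == 0) return(numeric())
  err <- .rnd_errors(rnd, .fp_dense(fps, rnd$nbits))
  rnd$bonus_scale * err / (sqrt(rnd$err_var) + 1e-8)
}

#' Train the RND predictor on a batch of fingerprints
#'
#' One Adam step on the mean squared error between predictor and target
#' outputs, plus an update of the running error statistics used for bonus
#' normalization.
#'
#' @param rnd an [rnd_state()].
#' @param fps list of fingerprints.
#' @return the updated `rnd_state`.
#' @export
rnd_update <- function(rnd, fps) {
  stopifnot(inherits(rnd, "rnd_state"))
  if (length(fps) == 0) return(rnd)
  x <- .fp_dense(fps, rnd$nbits)
  n <- ncol(x)
  t_out <- .rnd_forward(rnd$target, x)$out
  fwd <- .rnd_forward(rnd$predictor, x)
  diff <- fwd$out - t_out                       # emb x n
  # running stats on raw squared errors (Welford over batches)
  err <- colSums(diff^2)
  for (e in err) {
    rnd$err_n <- rnd$err_n + 1
    d <- e - rnd$err_mean
    rnd$err_mean <- rnd$err_mean + d / rnd$err_n
    rnd$err_var <- if (rnd$err_n > 1) {
      ((rnd$err_n - 2) * rnd$err_var + d * (e - rnd$err_mean)) / (rnd$err_n - 1)
    } else rnd$err_var
  }
  # gradients of mean_n ||diff||^2
  gout <- 2 * diff / n                          # emb x n
  gW2 <- gout %*% t(fwd$h)
  gb2 <- rowSums(gout)
  gh <- t(rnd$predictor$W2) %*% gout
  gh[fwd$h <= 0] <- 0
  gW1 <- gh %*% t(x)
  gb1 <- rowSums(gh)
  grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  st <- .adam_step(rnd$predictor, grads, rnd$opt, lr = rnd$lr)
  rnd$predictor <- st$params
  rnd$opt <- st$state
  rnd
}
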