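# The autoregressive policy: a GRU next-token model over SMILES tokens.
# Forward sampling, sequence log-probabilities and gradients live in
# compiled code; this file owns parameter initialization, the Adam
# optimizer, cross-entropy pretraining and checkpointing.

#' Policy architecture configuration
#'
#' @param emb_dim token embedding size.
#' @param hidden_dim GRU hidden state size.
#' @param n_layers number of stacked GRU layers.
#' @param max_len maximum number of generated tokens per molecule
#'   (sequences are truncated there; the truncated prefix is scored as-is
#'   and is usually invalid, hence rewarded 0).
#' @return a `clm_config` list.
#' @export
clm_config <- function(emb_dim = 64L, hidden_dim = 256L, n_layers = 2L,
                       max_len = 100L) {
  structure(list(emb_dim = as.integer(emb_dim),
                 hidden_dim = as.integer(hidden_dim),
                 n_layers = as.integer(n_layers),
                 max_len = as.integer(max_len)),
            class = "clm_config")
}

#' Create a freshly initialized policy
#'
#' Weights are drawn uniformly from `(-k, k)` with `k = 1/sqrt(hidden_dim)`
#' (the usual fan-in scaling); biases start at zero. At every state the
#' next-token probabilities form a proper distribution by construction
#' (softmax output layer).
#'
#' @param vocab a [build_vocabulary()] vocabulary.
#' @param config a [clm_config()].
#' @param seed integer seed for the initialization draw.
#' @return a `clm_policy` object.
#' @export
clm_policy <- function(vocab, config = clm_config(), seed = 1L) {
  stopifnot(inherits(vocab, "clm_vocabulary"))
  V <- length(vocab$tokens)
  E <- config$emb_dim; H <- config$hidden_dim; L <- config$n_layers
  k <- 1 / sqrt(H)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed %% 2147483647))
  rmat <- function(r, c, kk) matrix(stats::runif(r * c, -kk, kk), r, c)
  params <- list(
    emb = rmat(E, V, 1 / sqrt(E)),
    Wx = lapply(seq_len(L), function(l) rmat(3 * H, if (l == 1) E else H, k)),
    Wh = lapply(seq_len(L), function(l) rmat(3 * H, H, k)),
    bx = lapply(seq_len(L), function(l) numeric(3 * H)),
    bh = lapply(seq_len(L), function(l) numeric(3 * H)),
    Wo = rmat(V, H, k),
    bo = numeric(V)
  )
  structure(list(vocab = vocab, config = config, params = params),
            class = "clm_policy")
}

#' @export
print.clm_policy <- function(x, ...) {
  cfg <- x$config
  cat("<clm_policy> GRU ", cfg$n_layers, "x", cfg$hidden_dim,
      ", embedding ", cfg$emb_dim, ", vocabulary ",
      length(x$vocab$tokens), "\n", sep = "")
  invisible(x)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Sample a batch of molecules from a policy
#'
#' Autoregressive sampling, BOS-initialized, stopping at EOS or `max_len`
#' tokens. A fixed seed reproduces the batch exactly. The reported log
#' probability of each sequence equals [sequence_log_prob()] of that
#' sequence.
#'
#' @param policy a `clm_policy`.
#' @param n number of molecules (0 gives an empty batch).
#' @param seed integer sampling seed.
#' @param max_len optional override of the configured maximum length.
#' @return list with `smiles` (character), `seqs` (list of token-index
#'   vectors, EOS-terminated unless truncated), `logp` (numeric).
#' @export
sample_batch <- function(policy, n, seed = 1L, max_len = NULL) {
  stopifnot(inherits(policy, "clm_policy"), n >= 0)
  if (n == 0) {
    return(list(smiles = character(), seqs = list(), logp = numeric()))
  }
  ml <- if (is.null(max_len)) policy$config$max_len else as.integer(max_len)
  res <- .clm_sample_cpp(policy$params, as.integer(n), ml,
                         policy$vocab$bos, policy$vocab$eos, as.double(seed))
  seqs <- lapply(seq_len(n), function(i) {
    res$tokens[i, seq_len(res$lengths[i]), drop = TRUE]
  })
  smiles <- vapply(seqs, detokenize, character(1), vocab = policy$vocab)
  list(smiles = smiles, seqs = seqs, logp = as.numeric(res$logp))
}

#' Log-probability of token sequences under a policy
#'
#' Sum over steps of the log conditional probability of each token
#' (including the terminating EOS where present), starting from BOS.
#'
#' @param policy a `clm_policy`.
#' @param seqs list of token-index vectors (as produced by [tokenize()] or
#'   [sample_batch()]), or a single integer vector.
#' @return numeric vector of non-positive log-probabilities.
#' @export
sequence_log_prob <- function(policy, seqs) {
  if (is.numeric(seqs)) seqs <- list(as.integer(seqs))
  if (length(seqs) == 0) return(numeric())
  if (any(lengths(seqs) > policy$config$max_len)) {
    stop("sequence longer than the configured max_len")
  }
  p <- .pad_sequences(seqs)
  as.numeric(.clm_logprob_cpp(policy$params, p$tokens, p$lengths,
                              policy$vocab$bos))
}

#' Next-token distribution at a state
#'
#' @param policy a `clm_policy`.
#' @param prefix integer vector of token indices already emitted (may be
#'   empty for the initial state).
#' @return numeric vector of probabilities over the vocabulary (sums to 1).
#' @export
next_token_probs <- function(policy, prefix = integer()) {
  as.numeric(.clm_step_probs_cpp(policy$params, as.integer(prefix),
                                 policy$vocab$bos))
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(params) {
  zero <- function(x) {
    if (is.list(x)) lapply(x, zero)
    else if (is.matrix(x)) matrix(0, nrow(x), ncol(x))
    else numeric(length(x))
  }
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

.adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(upd, p, g, m, v)
      return(list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  out <- Map(upd, params, grads, state$m, state$v)
  list(params = lapply(out, `[[`, "p"),
       state = list(m = lapply(out, `[[`, "m"),
                    v = lapply(out, `[[`, "v"), t = t))
}

# one weighted-log-likelihood gradient + Adam update; the workhorse behind
# both pretraining and the REINFORCE step. `weights` of 1 give plain
# cross-entropy; REINFORCE passes (possibly adjusted) shaped rewards.
.policy_update <- function(policy, opt, seqs, weights, lr,
                           extra_grads = NULL, extra_scale = 0) {
  p <- .pad_sequences(seqs)
  g <- .clm_grad_cpp(policy$params, p$tokens, p$lengths, policy$vocab$bos,
                     as.numeric(weights))
  grads <- g$grads
  if (!is.null(extra_grads) && extra_scale != 0) {
    grads <- .grad_axpy(grads, extra_grads, extra_scale)
  }
  st <- .adam_step(policy$params, grads, opt, lr = lr)
  policy$params <- st$params
  list(policy = policy, opt = st$state, loss = g$loss, logp = g$logp)
}

# grads + a * extra, recursively over the parameter list
.grad_axpy <- function(grads, extra, a) {
  Map(function(g, e) {
    if (is.list(g)) Map(function(gi, ei) gi + a * ei, g, e) else g + a * e
  }, grads, extra)
}

# ---- pretraining ---------------------------------------------------------

#' Pretrain a policy on a SMILES corpus by cross-entropy
#'
#' Minimizes the mean per-sequence negative log-likelihood of the corpus
#' (teacher-forced next-token prediction) with Adam. Deterministic for a
#' fixed seed.
#'
#' @param policy a freshly created or previously trained `clm_policy`.
#' @param corpus character vector of SMILES; every string must be covered
#'   by the policy's vocabulary.
#' @param epochs passes over the corpus.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param seed shuffling seed.
#' @return list with the trained `policy` and `nll_trace`, the mean
#'   per-sequence NLL (nats) after each epoch.
#' @export
pretrain <- function(policy, corpus, epochs = 10L, batch_size = 64L,
                     lr = 1e-3, seed = 1L) {
  stopifnot(inherits(policy, "clm_policy"), length(corpus) > 0)
  seqs <- lapply(corpus, tokenize, vocab = policy$vocab)
  too_long <- lengths(seqs) > policy$config$max_len
  if (any(too_long)) {
    stop(sum(too_long), " corpus sequence(s) exceed max_len")
  }
  opt <- .adam_init(policy$params)
  nll_trace <- numeric(epochs)
  n <- length(seqs)
  for (ep in seq_len(epochs)) {
    old <- .save_rng()
    set.seed(.derive_seed(seed, ep, stream = 1L))
    ord <- sample.int(n)
    .restore_rng(old)
    tot <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      res <- .policy_update(policy, opt, seqs[idx], rep(1, length(idx)), lr)
      policy <- res$policy; opt <- res$opt
      if (!is.finite(res$loss)) stop("pretraining diverged: non-finite NLL")
      tot <- tot + res$loss * length(idx)
    }
    nll_trace[ep] <- tot / n
  }
  list(policy = policy, nll_trace = nll_trace)
}

# ---- checkpointing -------------------------------------------------------

#' Save / load a policy checkpoint
#'
#' A single-file container holding the vocabulary, architecture config and
#' parameters, with a format version for forward compatibility.
#'
#' @param policy a `clm_policy`.
#' @param path file path.
#' @return `load_policy` returns the `clm_policy`.
#' @export
save_policy <- function(policy, path) {
  stopifnot(inherits(policy, "clm_policy"))
  obj <- list(format = "molexplore-clm", version = 1L,
              vocab = policy$vocab, config = policy$config,
              params = policy$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_policy
#' @export
load_policy <- function(path) {
  force(path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("not a molexplore policy checkpoint: ", path, call. = FALSE)
  })
  if (!identical(obj$format, "molexplore-clm")) {
    stop("not a molexplore policy checkpoint: ", path)
  }
  structure(list(vocab = obj$vocab, config = obj$config, params = obj$params),
            class = "clm_policy")
}
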