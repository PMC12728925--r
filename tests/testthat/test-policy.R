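test_that("next-token distributions are proper at random states", {
  pol <- fixture_policy()
  v <- fixture_vocab()
  set.seed(21)
  for (i in 1:100) {
    k <- sample(0:8, 1)
    prefix <- if (k == 0) integer() else sample(4:length(v$tokens), k, replace = TRUE)
    p <- next_token_probs(pol, prefix)
    expect_length(p, length(v$tokens))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("a zero-parameter policy is uniform: closed-form log-probability", {
  v <- fixture_vocab()
  pol <- clm_policy(v, clm_config(emb_dim = 8, hidden_dim = 8, n_layers = 1,
                                  max_len = 30), seed = 1)
  pol$params <- rapply(pol$params, function(x) x * 0, how = "replace")
  V <- length(v$tokens)
  seqs <- lapply(c("CCO", "c1ccccc1"), tokenize, vocab = v)
  lp <- sequence_log_prob(pol, seqs)
  expect_equal(lp, lengths(seqs) * log(1 / V), tolerance = 1e-12)
})

test_that("sampling is seeded-deterministic and reports exact log-probs", {
  pol <- fixture_policy()
  s1 <- sample_batch(pol, 20, seed = 123)
  s2 <- sample_batch(pol, 20, seed = 123)
  s3 <- sample_batch(pol, 20, seed = 124)
  expect_identical(s1, s2)
  expect_false(identical(s1$smiles, s3$smiles))
  expect_equal(sequence_log_prob(pol, s1$seqs), s1$logp, tolerance = 1e-12)
  expect_true(all(s1$logp <= 0))

  empty <- sample_batch(pol, 0)
  expect_length(empty$smiles, 0)
})

test_that("analytic gradients match finite differences on a tiny model", {
  v <- build_vocabulary(c("CCO", "CN", "c1ccccc1"))
  pol <- clm_policy(v, clm_config(emb_dim = 3, hidden_dim = 4, n_layers = 2,
                                  max_len = 20), seed = 3)
  seqs <- lapply(c("CCO", "CN", "c1ccccc1"), tokenize, vocab = v)
  w <- c(1, 0.25, 0.8)
  pd <- molexplore:::.pad_sequences(seqs)
  g <- molexplore:::.clm_grad_cpp(pol$params, pd$tokens, pd$lengths, v$bos, w)
  lossfn <- function(params) {
    lp <- molexplore:::.clm_logprob_cpp(params, pd$tokens, pd$lengths, v$bos)
    -sum(w * lp) / length(w)
  }
  expect_equal(g$loss, lossfn(pol$params), tolerance = 1e-12)
  set.seed(4)
  eps <- 1e-5
  flat_names <- list(c("emb"), c("Wo"), c("bo"), c("Wx", 1), c("Wh", 2),
                     c("bx", 1), c("bh", 2))
  for (spec in flat_names) {
    p2 <- pol$params
    x <- if (length(spec) == 1) p2[[spec]] else p2[[spec[1]]][[as.integer(spec[2])]]
    ana <- if (length(spec) == 1) g$grads[[spec]] else g$grads[[spec[1]]][[as.integer(spec[2])]]
    for (rep in 1:4) {
      i <- sample(length(x), 1)
      xp <- x; xp[i] <- x[i] + eps
      if (length(spec) == 1) p2[[spec]] <- xp else p2[[spec[1]]][[as.integer(spec[2])]] <- xp
      l1 <- lossfn(p2)
      xp[i] <- x[i] - eps
      if (length(spec) == 1) p2[[spec]] <- xp else p2[[spec[1]]][[as.integer(spec[2])]] <- xp
      l2 <- lossfn(p2)
      expect_equal(ana[i], (l1 - l2) / (2 * eps), tolerance = 1e-5)
    }
  }
})

test_that("pretraining reduces NLL and can memorize a single string", {
  v <- fixture_vocab()
  pol <- clm_policy(v, clm_config(emb_dim = 16, hidden_dim = 32, n_layers = 1,
                                  max_len = 30), seed = 2)
  res <- pretrain(pol, rep("CC(N)CO", 64), epochs = 40, batch_size = 16,
                  lr = 5e-3, seed = 1)
  expect_lt(utils::tail(res$nll_trace, 1), 0.1)  # memorization limit
  expect_lt(utils::tail(res$nll_trace, 1), res$nll_trace[1])
})

test_that("pretraining NLL sits between entropy floor and uniform ceiling", {
  res <- fixture_pretrained()
  v <- fixture_vocab()
  corpus <- fixture_corpus()
  final <- utils::tail(res$nll_trace, 1)
  mean_len <- mean(lengths(lapply(corpus, tokenize, vocab = v)))
  uniform_nll <- mean_len * log(length(v$tokens))
  expect_lt(final, uniform_nll)
  expect_gt(final, 0)
  expect_lte(min(res$nll_trace), res$nll_trace[1])
})

test_that("sampled molecules from the pretrained policy are mostly valid", {
  s <- sample_batch(fixture_policy(), 500, seed = 99)
  expect_gte(mean(smiles_is_valid(s$smiles)), 0.95)
})

test_that("checkpoints round-trip", {
  pol <- fixture_policy()
  path <- withr::local_tempfile(fileext = ".rds")
  save_policy(pol, path)
  pol2 <- load_policy(path)
  expect_equal(pol2$params, pol$params)
  expect_identical(sample_batch(pol2, 5, seed = 1)$smiles,
                   sample_batch(pol, 5, seed = 1)$smiles)
  expect_error(load_policy(withr::local_tempfile(lines = "x")), "checkpoint")
})

test_that("overlong sequences are rejected for scoring", {
  v <- fixture_vocab()
  pol <- clm_policy(v, clm_config(emb_dim = 8, hidden_dim = 8, n_layers = 1,
                                  max_len = 5), seed = 1)
  expect_error(sequence_log_prob(pol, list(rep(4L, 10))), "max_len")
})
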