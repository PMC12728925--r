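test_that("population initialization copies or perturbs the base policy", {
  base <- fixture_policy()
  pop0 <- init_population(base, 3, "independent", coop_config(), seed = 1)
  for (p in pop0$policies) expect_equal(p$params, base$params, tolerance = 0)

  popn <- init_population(base, 3, "noise", coop_config(noise_sigma = 0.02),
                          seed = 1)
  for (p in popn$policies) {
    expect_gt(max(abs(p$params$Wo - base$params$Wo)), 0)
  }
  expect_false(identical(popn$policies[[1]]$params$Wo,
                         popn$policies[[2]]$params$Wo))
  popn2 <- init_population(base, 3, "noise", coop_config(noise_sigma = 0.02),
                           seed = 1)
  expect_equal(popn, popn2)
  # zero noise degenerates to exact copies
  popz <- init_population(base, 2, "noise", coop_config(noise_sigma = 0),
                          seed = 1)
  expect_equal(popz$policies[[1]]$params, base$params, tolerance = 0)
  expect_error(init_population(base, 2, "telepathy"), "unknown strategy")
})

test_that("popnorm adjustment centers returns across the population", {
  expect_equal(popnorm_adjust(list(c(1, 1), c(1, 1))),
               list(c(0, 0), c(0, 0)))
  expect_equal(popnorm_adjust(list(2, 0)), list(1, -1))
  set.seed(8)
  rets <- lapply(1:4, function(i) stats::runif(sample(1:5, 1)))
  adj <- popnorm_adjust(rets)
  expect_equal(sum(unlist(adj)), 0)
  expect_equal(lengths(adj), lengths(rets))
})

test_that("shared-buffer bonus rewards only novel states", {
  buf <- replay_buffer(10)
  buf <- buffer_insert(buf, "CCO", 0.5, 1L)
  expect_equal(shared_bonus(buf, c("CCO", "CCN", NA), 0.1), c(0, 0.1, 0))
  expect_equal(shared_bonus(buf, "CCN", 0), 0)  # bonus 0 -> plain shared
})

test_that("specialization losses match their closed forms", {
  # single agent: every auxiliary loss vanishes
  for (kind in c("ent_s", "ce_s", "diff_s", "diff_n")) {
    out <- specialization_loss(kind, matrix(-1, 3, 1), c(2, 2, 2), rep(1, 3), 1)
    expect_equal(out$value, 0)
    expect_equal(out$coef, numeric(3))
  }
  # uniform confidence: entropy is log(N) per state
  logp <- matrix(-5, nrow = 4, ncol = 3)
  out <- specialization_loss("ent_s", logp, rep(10, 4), c(1, 1, 2, 3), 1)
  expect_equal(out$value, log(3))
  # near-one-hot confidence on the originating agent: cross-entropy near 0
  logp2 <- matrix(-200, 2, 2)
  logp2[1, 1] <- -1; logp2[2, 2] <- -1
  out2 <- specialization_loss("ce_s", logp2, c(5, 5), c(1, 2), 1)
  expect_lt(out2$value, 1e-6)
  # diff_s: own-state uncertainty minus other-state uncertainty
  logp3 <- rbind(c(-2, -8), c(-6, -4))
  out3 <- specialization_loss("diff_s", logp3, c(2, 2), c(1, 2), 1)
  expect_equal(out3$value, (2 / 2) - (6 / 2))
  # diff_n gradient only touches own states
  out4 <- specialization_loss("diff_n", logp3, c(2, 2), c(1, 2), 1)
  expect_equal(out4$coef[2], 0)
  expect_lt(out4$coef[1], 0)
})

test_that("the determinant diversity score behaves like a diversity measure", {
  e_same <- rbind(c(-1, -2, -3), c(-1, -2, -3))
  expect_equal(dvd_score(e_same), -30)  # singular kernel hits the floor

  e <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(dvd_score(e[c(2, 1, 3), ]), dvd_score(e))  # permutation invariant

  # moving two embeddings apart monotonically increases the score
  scores <- vapply(seq(0.5, 3, by = 0.5), function(d) {
    dvd_score(rbind(c(0, 0), c(d, 0)), bandwidth = 1)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("behavior embeddings are deterministic log-probs on the probe set", {
  pol <- fixture_policy()
  probes <- sample_batch(pol, 8, seed = 5)$seqs
  e1 <- behavior_embedding(pol, probes)
  expect_length(e1, 8)
  expect_equal(e1, sequence_log_prob(pol, probes))
})

test_that("purge keeps buffers pairwise disjoint", {
  bufs <- list(replay_buffer(50), replay_buffer(50), replay_buffer(50))
  set.seed(9)
  mols <- paste0("C", strrep("C", sample(1:30, 1000, replace = TRUE)))
  for (i in seq_len(1000)) {
    ag <- sample(1:3, 1)
    bufs <- purge_insert(bufs, ag, mols[i], stats::runif(1), i)
  }
  for (a in 1:2) for (b in (a + 1):3) {
    expect_length(intersect(bufs[[a]]$smiles, bufs[[b]]$smiles), 0)
  }
})

test_that("a 1-agent independent population reproduces the single-agent runner", {
  pol <- fixture_policy()
  task <- fixture_task2()
  rec1 <- rl_run(pol, task, budget = 96, cfg = desk_config(), seed = 3)
  pop <- init_population(pol, 1, "independent", coop_config(), seed = 3)
  recP <- run_cooperative(pop, task, 96, desk_config(), seed = 3)
  expect_identical(recP$agents[[1]]$samples, rec1$samples)
  expect_identical(recP$union_per_target_max, rec1$per_target_max)
})

test_that("the union score dominates every single agent's score", {
  pol <- fixture_policy()
  task <- fixture_task2()
  pop <- init_population(pol, 3, "independent", coop_config(), seed = 2)
  rec <- run_cooperative(pop, task, 96, desk_config(), seed = 2)
  for (a in rec$agents) {
    expect_true(all(rec$union_per_target_max >= a$per_target_max))
    expect_gte(rec$union_score, a$score)
  }
})

test_that("shared strategy draws replay from one common buffer", {
  pol <- fixture_policy()
  task <- fixture_task2()
  pop <- init_population(pol, 2, "shared", coop_config(), seed = 4)
  rec <- run_cooperative(pop, task, 96, desk_config(), seed = 4)
  expect_false(is.null(rec$shared_buffer))
  expect_gt(length(rec$shared_buffer$smiles), 0)
})
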