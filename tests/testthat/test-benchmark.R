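test_that("the oracle returns the similarity to the nearest target", {
  task <- fixture_task2()
  # a target molecule scores exactly 1
  expect_equal(oracle_reward(task$targets[1], task), 1)
  # non-canonical spelling of a target also scores 1
  expect_equal(oracle_reward(task$targets, task), c(1, 1))
  # invalid SMILES scores 0
  expect_equal(oracle_reward("C1CC", task), 0)
  # the max over per-target similarities is used
  sims <- molexplore:::.task_similarities(
    validate_and_canonicalize("CCOCC"), task)
  expect_equal(oracle_reward("CCOCC", task), max(sims))
})

test_that("tanimoto oracle kind selects fingerprint similarity", {
  task <- task_spec("fp", c("CCO", "c1ccccc1N"), "tanimoto")
  fp_m <- ecfp4("CCOC")[[1]]
  expected <- max(tanimoto(fp_m, task$target_fps[[1]]),
                  tanimoto(fp_m, task$target_fps[[2]]))
  expect_equal(oracle_reward("CCOC", task), expected)
})

test_that("external oracles plug in through a callback", {
  calls <- new.env(); calls$n <- 0
  fn <- function(smiles) { calls$n <- calls$n + 1; rep(0.42, length(smiles)) }
  task <- task_spec("ext", c("CCO", "c1ccccc1"), "external", oracle_fn = fn)
  expect_equal(oracle_reward("CCN", task), 0.42)
  expect_gt(calls$n, 0)
  expect_error(task_spec("ext2", c("CCO", "CCN"), "external"), "oracle")
})

test_that("task score is the product of per-target maxima", {
  expect_equal(task_score(c(1, 1, 1)), 1)
  expect_equal(task_score(c(0, 0)), 0)
  expect_equal(task_score(c(0.8, 0.5)), 0.4)
  tr <- score_trace(3)
  expect_equal(task_score(tr), 0)
  expect_error(task_score(numeric()), "targets")
})

test_that("benchmark sum aggregates task scores", {
  expect_equal(benchmark_sum(rep(1, 4)), 4)
  expect_equal(benchmark_sum(rep(0, 4)), 0)
  expect_equal(benchmark_sum(c(0.64, 0.44, 0.28, 0.25)), 1.61)
})

test_that("task files load with schema validation", {
  task <- fixture_task2()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_task(task, path)
  back <- load_task(path)
  expect_equal(back$targets, task$targets)
  expect_equal(back$oracle_kind, task$oracle_kind)

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name = "x", oracle = "levenshtein",
                        targets = list("CCO")), bad)
  expect_error(load_task(bad), "targets")
  yaml::write_yaml(list(name = "x", oracle = "nope",
                        targets = list("CCO", "CCN")), bad)
  expect_error(load_task(bad), "oracle")
  yaml::write_yaml(list(name = "x", oracle = "levenshtein",
                        targets = list("CCO", "OCC")), bad)
  expect_error(load_task(bad), "duplicate")
  yaml::write_yaml(list(oracle = "levenshtein",
                        targets = list("CCO", "CCN")), bad)
  expect_error(load_task(bad), "name")
  expect_error(load_task("/nonexistent/task.yaml"), "not found")
})

test_that("SEDiv matches its stated edge cases", {
  # duplicates collapse to one sphere center
  expect_equal(sphere_exclusion_diversity(rep("CC(O)Nc1ccc(O)cc1", 100)),
               0.01)
  # pairwise-dissimilar molecules are all centers
  mols <- c("CCCCCCCC", "c1ccccc1", "NNNN", "OCO")
  fps <- ecfp4(mols)
  pair_sims <- molexplore:::.tanimoto_cross(fps, fps)
  diag(pair_sims) <- 0
  if (all(pair_sims < 0.65)) {
    expect_equal(sphere_exclusion_diversity(mols), 1)
  }
  expect_error(sphere_exclusion_diversity(character()), "molecules")
})

test_that("SEDiv agrees with an independent greedy re-scan", {
  # independent oracle: direct quadratic greedy scan over fingerprints
  sediv_oracle <- function(mols, threshold = 0.65) {
    fps <- ecfp4(mols)
    centers <- list()
    for (fp in fps) {
      covered <- FALSE
      for (cf in centers) {
        if (tanimoto(fp, cf) >= threshold) { covered <- TRUE; break }
      }
      if (!covered) centers[[length(centers) + 1]] <- fp
    }
    length(centers) / length(mols)
  }
  set.seed(31)
  corpus <- fixture_corpus_raw()
  for (rep in 1:3) {
    mols <- validate_and_canonicalize(sample(corpus, 20))
    expect_equal(sphere_exclusion_diversity(mols, sample_size = 1000),
                 sediv_oracle(mols))
  }
})

test_that("SEDiv subsamples deterministically above the sample size", {
  corpus <- validate_and_canonicalize(fixture_corpus_raw()[1:80])
  a <- sphere_exclusion_diversity(corpus, sample_size = 50, seed = 7)
  b <- sphere_exclusion_diversity(corpus, sample_size = 50, seed = 7)
  expect_identical(a, b)
})
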