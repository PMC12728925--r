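# Shared desk-scale fixtures, built once per test session. The corpus,
# benchmark tasks and pretrained policy define the study conditions used
# by every learning and scaling test: a 2000-molecule toy corpus (up to
# 28 heavy atoms of C/N/O chains, branches and occasional rings, so
# chance rediscovery of a target is rare), a 4-task suite with 2/3/3/4
# targets at inter-target similarity <= 0.3, and a 1-layer GRU
# (embedding 32, hidden 64) pretrained for 12 epochs on the
# target-pruned split. RL runs use the desk-scale engine configuration
# (batch 16, Adam lr 0.01), sized so an agent's collapse onto a target
# saturates within the ~60 optimization steps a 1000-molecule budget
# allows.

.fx <- new.env(parent = emptyenv())

fixture_corpus_raw <- function() {
  if (is.null(.fx$corpus_raw)) {
    .fx$corpus_raw <- generate_toy_corpus(2000, max_heavy_atoms = 28,
                                          p_ring = 0.1, seed = 11)
  }
  .fx$corpus_raw
}

desk_config <- function(...) {
  rl_config(batch_size = 16, lr = 0.01, ...)
}

# suite of 4 multi-target tasks plus one single-target task; the returned
# corpus excludes every target (rediscovery, not recall)
fixture_bench <- function() {
  if (is.null(.fx$bench)) {
    suite <- toy_benchmark_suite(fixture_corpus_raw(), seed = 11)
    single <- generate_toy_task(suite$corpus, n_targets = 1,
                                oracle_kind = "levenshtein", seed = 5,
                                name = "toy-single")
    .fx$bench <- list(tasks = suite$tasks, task_single = single$task,
                      corpus = single$corpus)
  }
  .fx$bench
}

fixture_corpus <- function() fixture_bench()$corpus

fixture_vocab <- function() {
  if (is.null(.fx$vocab)) .fx$vocab <- build_vocabulary(fixture_corpus())
  .fx$vocab
}

fixture_pretrained <- function() {
  if (is.null(.fx$pretrained)) {
    pol <- clm_policy(fixture_vocab(),
                      clm_config(emb_dim = 32, hidden_dim = 64,
                                 n_layers = 1, max_len = 90),
                      seed = 1)
    .fx$pretrained <- pretrain(pol, fixture_corpus(), epochs = 12,
                               batch_size = 64, lr = 3e-3, seed = 1)
  }
  .fx$pretrained
}

fixture_policy <- function() fixture_pretrained()$policy

# first suite task: 2 structurally dissimilar targets, Levenshtein oracle
fixture_task2 <- function() fixture_bench()$tasks[[1]]

fixture_task_single <- function() fixture_bench()$task_single

# a tiny two-arm vocabulary/policy for bandit-style diagnostics
bandit_policy <- function(seed = 9) {
  v <- structure(list(tokens = c("<pad>", "<bos>", "<eos>", "A", "B"),
                      index = stats::setNames(1:5, c("<pad>", "<bos>",
                                                     "<eos>", "A", "B")),
                      pad = 1L, bos = 2L, eos = 3L),
                 class = "clm_vocabulary")
  clm_policy(v, clm_config(emb_dim = 8, hidden_dim = 16, n_layers = 1,
                           max_len = 4), seed = seed)
}

bandit_config <- function(lr = 0.05) {
  rl_config(batch_size = 16, shaping = shaping_config(sigma = 0, alpha = 1),
            lr = lr, replay_k = 0, canonicalize = FALSE,
            reward_fn = function(s) as.numeric(s == "A"))
}
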