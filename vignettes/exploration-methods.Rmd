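---
title: "Test-time training of a chemical language model for multi-target exploration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-time training of a chemical language model for multi-target exploration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

De novo molecular design with a chemical language model (CLM) and
reinforcement learning routinely suffers from *mode collapse*: once the
policy finds one high-reward region of chemical space it stops exploring,
even though practical drug discovery wants *several* structurally distinct
candidate series against the same target. `molexplore` implements a
framework for studying this failure and the remedies for it:

* a SMILES CLM — a recurrent next-token policy — pretrained by
  cross-entropy on a molecule corpus;
* a REINFORCE-based optimizer with prior-regularized reward reshaping,
  prioritized experience replay and optional exploration mechanisms
  (random network distillation, a diversity filter);
* a multi-target *rediscovery* benchmark whose oracle returns the
  similarity of a generated molecule to the nearest of 2–4 dissimilar
  target molecules, scored by the product over targets of the run-wide
  maximum similarity achieved;
* population strategies that run several agents on one task, either
  independently or coupled through buffers, bonuses or auxiliary losses;
* scaling experiments over the number of agents and over a single agent's
  sampling budget, with log-linear fits.

The framing is *test-time training* (TTT): the pretrained generator's
parameters are updated per task at deployment, and the question is how
benchmark performance scales as TTT is scaled — by population size or by
training time.

# The model

## Policy

The policy is an autoregressive GRU over SMILES tokens
(`build_vocabulary()`, `clm_policy()`). Multi-character units — bracket
atoms, `Cl`/`Br`, `%nn` ring labels — are single tokens. A sequence is
BOS-initialized and EOS-terminated, with probability
$P(X)=\prod_t P(x_t \mid x_{<t})$; `sequence_log_prob()` returns
$\sum_t \log P(x_t\mid x_{<t})$ including the EOS step. Pretraining
(`pretrain()`) minimizes the mean per-sequence negative log-likelihood with
Adam. The default architecture (embedding 64, hidden 256, 2 layers,
`max_len` 100) is configurable; the test fixtures use a smaller
1×64 network that trains in seconds on a toy grammar. Sampling, scoring
and backpropagation-through-time are implemented in compiled code under
`src/`; the analytic gradients are verified against finite differences in
the test suite.

Sequences that reach `max_len` without EOS are truncated and scored as-is;
the truncated prefix is usually invalid SMILES and so earns reward 0.

## Reward shaping and the update

Each sampled molecule receives the raw oracle reward $R \in [0,1]$ and is
reshaped against the frozen pretrained prior:

$$R_\text{shaped}(\tau) = \operatorname{clip}\big(R(\tau) + \sigma \log
\pi_\text{prior}(\tau)\big)_+^{\alpha}$$

with defaults $\sigma = 0.001$, $\alpha = 3$. The clip at zero (the only
bound applied) keeps the reshaped reward non-negative; $0^\alpha$ is 0.
With $\sigma=0,\alpha=1$ the engine is vanilla REINFORCE. The update
minimizes $-\tfrac1B\sum_i R_\text{shaped}(\tau_i)\log\pi_\theta(\tau_i)$,
whose gradient is the reward-weighted REINFORCE estimator. Off-policy
augmentation draws `replay_k` trajectories per step from a bounded replay
buffer (one entry per canonical SMILES, best reward kept, lowest-reward
eviction), with selection probability proportional to reward and without
replacement within a draw; replayed trajectories get their log-probability
recomputed under the current policy inside the gradient call, so no
importance weights are carried.

Exploration mechanisms operate on the raw reward before reshaping: the
diversity filter zeroes the reward of any previously generated canonical
SMILES, and the RND bonus adds `bonus_scale` times the running-normalized
squared prediction error of a trained predictor network against a frozen
random target network on the molecule's fingerprint. When both are active
the filter is applied first and the bonus added afterwards, so a repeated
molecule can still earn a (vanishing) novelty bonus.

## Benchmark

A task (`task_spec()`) names 2–4 valid, pairwise-distinct target molecules
and an oracle kind. The oracle reward is
$R(m)=\max_t \operatorname{sim}(m, m_t)$ — similarity to the *nearest*
target — with either normalized Levenshtein similarity
$1 - \mathrm{LD}(a,b)/\max(|a|,|b|)$ on canonical SMILES (the string-edit
benchmark flavor) or ECFP4/Tanimoto similarity (the fingerprint flavor).
An `external` oracle kind accepts a user callback scoring canonical
SMILES in $[0,1]$, the plug-in contract for predicted-bioactivity tasks;
the package deliberately does not ship a bioactivity model.

Performance is $\prod_t \max_i \operatorname{sim}(m_i, m_t)$ over *all*
molecules generated in a run (the per-target maxima are monotone, so the
score never decreases). Every sampled string — invalid or duplicate
included — counts against the molecule budget. Diversity is measured by
sphere-exclusion diversity: a seeded sample of up to 1000 distinct valid
molecules is scanned greedily, a molecule founds a new sphere center iff
its Tanimoto similarity to every center is strictly below 0.65 (ties fall
inside), and the center count is normalized by the scanned sample size.

## Population strategies

`run_cooperative()` runs $N$ agents round-robin (one batch per agent per
cycle, sequentially deterministic given seeds; agent $i$ uses seed
$s+i-1$). Twelve strategy names are recognized: `independent` plus eleven
couplings —

* buffer topology: `shared` (one replay buffer for all agents, a
  convergence *negative control*), `shared_bonus` (same, plus reward bonus
  `bonus_b` for molecules absent from the shared buffer), `purge` (insert
  only if absent from every other agent's buffer, keeping buffers pairwise
  disjoint);
* parameter noise: `noise` adds i.i.d. Gaussian noise (sd `noise_sigma`)
  to each agent's parameters at initialization;
* universal novelty: `rnd` gives every agent an RND bonus;
* auxiliary losses, weighted by `lambda` and computed on the cycle's
  pooled states: `ent_s` / `ce_s` act on the per-state agent-confidence
  (softmax over agents of sequence log-probability), minimizing its
  entropy or its cross-entropy against the state's originating agent;
  `diff_s` pushes an agent's per-token uncertainty down on its own states
  and up on the rest of the population's; `diff_n` maximizes the
  log-probability gap to the other agents on the agent's own states
  (all agents treated simultaneously, not sequentially);
* `dvd` maximizes the log-determinant of the RBF kernel matrix of the
  agents' behavior embeddings (log-probabilities on a frozen 32-sequence
  probe set sampled from the prior at initialization; bandwidth = median
  pairwise distance, log-determinant floored at −30);
* `popnorm` subtracts the population-mean return of the iteration from
  each agent's on-policy returns.

These couplings are known in the population-learning literature mostly as
one-line recipes; each is formalized here explicitly and kept behind a
single strategy interface so alternative formulations are drop-in. Two conventions are
worth stating: "policy uncertainty" of a state is its per-token-averaged
NLL, and per-state agent confidence is the softmax over agents of total
sequence log-probability.

Every coupling is scaled by an explicit coefficient, and the buffer
topologies and return normalization are gated by `lambda != 0`. This
gives a uniform reduction contract — any strategy with
`lambda = bonus_b = noise_sigma = 0` is bit-identical to `independent` —
that the test suite exercises for all eleven couplings.

# Synthetic data

`generate_toy_corpus()` emits distinct valid SMILES from a
validity-preserving grammar: chains of C/N/O with branches hung off
carbons only and occasional benzene/cyclohexane units, so every string
parses without rejection sampling. `generate_toy_task()` selects target
molecules from the corpus under a dissimilarity constraint and removes
them from the returned pretraining split (rediscovery, not recall);
`toy_benchmark_suite()` builds four tasks with 2, 3, 3 and 4 targets.

The fixture conditions were chosen once, for the property that makes the
benchmark meaningful — targets must be *distinct modes* of the reward
landscape that are rarely hit by chance:

* molecules of up to 28 heavy atoms with ring probability 0.1. Short
  molecules (the obvious toy choice) make the best-of-2000 random
  similarity to any target ≈ 0.9, saturating the benchmark before
  optimization starts; at 28 atoms the chance baseline drops to ≈ 0.6.
* targets are drawn from the upper length tercile, matched in length
  within 20%, and pairwise dissimilar (≤ 0.3) in ECFP4 Tanimoto *and* —
  for the string-edit oracle — in normalized Levenshtein similarity.
  Fingerprint dissimilarity alone leaves targets nearly equivalent in the
  oracle's own metric, merging the modes the task is supposed to keep
  apart. Length matching keeps the targets comparably difficult, so which
  one an agent collapses onto is decided by sampling noise rather than by
  a systematically easier target.

What the toy grammar does **not** emulate: realistic valence and
functional-group chemistry, stereochemistry, property distributions of
drug-like libraries, and the scale of a real pretraining set. Passing
tests on these fixtures validate the machinery — budget accounting,
metric, optimization, strategy contracts and scaling protocol — not
chemical realism; conclusions about real chemical space require a real
corpus and target sets, which the `.smi`/YAML interfaces accept directly.

# Desk-scale study conditions

The tests and the acceptance script shrink the full-scale protocol
(10,000-molecule budgets, up to 128 agents, 5 replicates) to desk scale:
budgets of 1000–4000 molecules, 1–8 agents, 3–5 replicates, a
2000-molecule corpus and a 1×64 GRU. Two engine settings differ from the
full-scale defaults, chosen so the desk protocol reproduces the
*structure* of the full experiment rather than an underpowered slice of
it: batch size 16 and Adam learning rate 0.01, which let a single agent's
collapse onto one target saturate within the ≈60 gradient steps a
1000-molecule budget allows (at full scale the same saturation happens
within a 10,000-molecule budget at batch 64). Replicate seeds are
`base_seed + 1000 r`; agent seeds are nested (`replicate seed + agent
index − 1`), which makes the agent sets for increasing $N$ supersets and
the union score exactly monotone in $N$ per replicate.

# Numerical choices and degenerate inputs

* Invalid SMILES are values (`NA`), never errors; they earn reward 0,
  consume budget, and are excluded from buffers, fingerprints and SEDiv.
* Tanimoto of two empty fingerprints is defined as 0 (unreachable for
  valid molecules). Open Babel's 4096-bit ECFP4 is folded to 2048 bits by
  OR-ing halves; canonicalization is Open Babel's dialect, fixed for a
  session — cross-toolkit byte identity is not promised, within-run
  consistency is.
* Levenshtein similarity of two empty strings is 1; the normalization is
  by the longer string, guaranteeing $[0,1]$.
* Replay sampling with an all-zero-reward buffer falls back to uniform;
  `k` at or above the buffer size returns the whole buffer.
* The DvD kernel is jittered (`1e-8` on the diagonal) if numerically
  singular, and the log-determinant is floored at −30 with zero gradient
  at the floor.
* All randomness flows through explicitly derived 31-bit seeds; the
  global R RNG state is saved and restored around every seeded operation,
  and compiled sampling uses its own Mersenne Twister stream, so runs are
  bit-reproducible from their config and seed.

# Known limitations

* The grammar corpus cannot measure chemical realism (see above).
* The desk-scale population-versus-budget comparison (4×1000 vs 1×4000)
  sits near a tie by construction — at matched total budget the full-scale
  protocol also shows only a modest advantage for populations at small
  $N$ — so its sign is sensitive to replicate noise.
* The `external` oracle contract is provided but no bioactivity model
  ships with the package.
* Open Babel accepts some SMILES that stricter toolkits reject; validity
  here means "parses under Open Babel".
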