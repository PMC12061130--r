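---
title: "Opponent actor-critic learning on multi-armed bandits: models, benchmarks, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opponent actor-critic learning on multi-armed bandits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opalbandit)
```

## The model

`opalbandit` simulates an opponent actor-critic model of striatal
reinforcement learning (OpAL*) and benchmarks it against standard bandit
agents. The model has three interacting parts.

**Critic.** A per-arm value estimate updated by the delta rule. On choosing
arm $a$ and observing reward $r$:

$$\delta = r - V(a), \qquad V(a) \leftarrow V(a) + \alpha_c\,\delta.$$

The reward prediction error (RPE) $\delta$ is the sole teaching signal for
everything downstream.

**Opponent Hebbian actors.** Two weight sets per arm, $G$ (Go, the D1
pathway) and $N$ (NoGo, the D2 pathway), learn from the same RPE in opposite
directions, and each update is scaled by the weight's own current value
(activity-dependent, multiplicative):

$$G(a) \leftarrow G(a) + \bar\alpha_G\, G(a)\, \delta, \qquad
  N(a) \leftarrow N(a) + \bar\alpha_N\, N(a)\, (-\delta),$$

with the annealed rate $\bar\alpha = \alpha / (1 + t/T)$, $t$ the number of
completed trials. The multiplicative term makes the rule recursive: weights
compound their own history, so $G$ becomes disproportionately sensitive to
runs of positive RPEs (upper tails of the outcome distribution) and $N$ to
runs of negative ones (lower tails). Weights start at 1, where the first
update reduces exactly to a standard actor update; they are floored at a
small positive constant and have no upper cap.

**Meta-critic and dopamine modulation.** A Beta distribution with counts
$(\eta, \zeta)$ tracks the probability that an RPE is positive — a summary
of environmental reward richness. Let $m$ and $s$ be the posterior mean and
standard deviation. When the interval $m \pm \phi s$ excludes $0.5$, a
dopamine-like gain

$$\rho = \operatorname{clip}\!\big(k\,(m - 0.5),\ -1,\ 1\big)$$

is applied; otherwise $\rho = 0$. Choice is a softmax over opponent
propensities

$$\mathrm{Act}(a) = \beta(1+\rho)\,G(a) - \beta(1-\rho)\,N(a),$$

so rich environments amplify the G pathway and sparse ones the N pathway.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `alpha_c` | critic learning rate | — | (0, 1] |
| `alpha_actor` | actor learning rate, tied across G/N | — | (0, 1] |
| `beta` | softmax temperature | — | any positive value; values below 1 matter on many-armed tasks |
| `k` | dopamine modulation strength | 20 | `k = 0` disables modulation |
| `phi` | meta-critic confidence multiplier | 1 | gates `rho` until the Beta posterior excludes 0.5 |
| `T_anneal` | annealing constant (trials) | 100 | effective rate `alpha / (1 + t/T)` |
| `v0` | critic initialization | resolved | 0.5 for Bernoulli; midpoint of arm means for Gaussian |
| `gn0` | actor initialization | 1 | identity of the multiplicative term |
| `weight_floor` | actor lower bound | 1e-6 | zero is absorbing under the multiplicative rule |
| `eta0`, `zeta0` | Beta prior counts | 1, 1 | uniform prior, `rho = 0` at the start |

The three shipped Bernoulli parameter presets, the Gaussian preset and the
simple `[0.25, 0.25, 0.25]` demonstration set (see `opal_presets()`) are
interpreted as `[alpha_c, alpha_actor, beta]` in that order, matching the
order in which the optimization protocol names them (critic learning rate,
actor learning rates, softmax temperature). This ordering is a documented
reading, not a printed fact.

A `flaws` argument reproduces a criticized legacy implementation exactly —
actors initialized at 0.5, weights capped at 10, annealing constant 10 —
for side-by-side comparisons with the corrected model.

## What the synthetic environments emulate

All inputs are generated internally; there is no external data.

* **Bernoulli bandits**: 0/1 rewards. The pinned-down benchmark condition is
  one 0.9 arm against nine 0.8 arms, a many-alternative discrimination task
  in which effective exploration is essential. The other two shipped
  Bernoulli presets are illustrative stand-ins for a wider benchmark family
  whose exact levels are not pinned down; they are flagged `unverified`.
* **Gaussian bandits**: real-valued rewards, means 0.8 vs 0.7. The outcome
  standard deviation is not pinned down by the benchmark description; we use
  `sigma = 0.1` for both arms, which gives substantial overlap between the
  outcome distributions (the closed-form probability that the worse arm
  out-draws the better one on a single pull is
  `pnorm(-0.1/(0.1*sqrt(2)))`, about 0.24) while keeping the means
  separable. The lower/higher reward-statistic variants shift both means by
  ±0.4, preserving the 0.1 gap.
* **Horizons and replications**: 1000 trials for Bernoulli and 2000 for
  Gaussian tasks, 1000 simulations per curve, matching the benchmark's
  stated Gaussian horizon and replication count; the Bernoulli horizon is a
  package default. Confidence bands are
  `mean ± 1.96 · SD / sqrt(n_sims)` across simulations — a deliberate,
  cheap normal approximation.

Passing benchmarks on these synthetic tasks show that the implementation has
the stated learning dynamics under stationary, independent-arm conditions.
They do not speak to nonstationary rewards, contextual structure, mixed
reward probability/magnitude settings, or fits to behavioral or neural data
— all out of scope.

## Numerical and design choices

* **Critic form.** Per-arm delta rule. A critic shared across arms is a
  meaningful variant but out of scope here.
* **Critic initialization.** For Gaussian tasks `v0` defaults to the
  midpoint of the configured arm means (0.75 for 0.8 vs 0.7): starting the
  critic inside the range of the reward statistics makes early RPEs
  consistently signed per arm, which is what lets the opponent actors
  discriminate overlapping distributions. A `forced_sampling` switch
  (one pull per arm before the policy is used) is provided as an
  alternative warm start.
* **`rho` mapping.** The exact functional form linking the Beta posterior
  to the dopamine gain is a declared design choice: gate at `phi` posterior
  standard deviations, then scale and clip to `[-1, 1]` so both softmax
  gains stay non-negative. `phi = 1` is a default, not a pinned-down value.
  The Gaussian benchmark results are insensitive to this block (disabling
  the meta-critic entirely leaves them statistically unchanged, which the
  acceptance suite verifies).
* **Ties and edge cases.** `delta = 0` routes to the negative meta-critic
  count (documented determinism; measure-zero for continuous rewards).
  UCB ties break uniformly at random. Softmax uses the max-shift for
  numerical stability. Bernoulli outcomes are encoded 0.0/1.0 so both
  environment kinds share one real-valued reward pathway.
* **Reproducibility.** Simulation `i` of a benchmark uses seed
  `base_seed + i` with a fresh agent, so results are invariant to the
  worker count. The compiled episode engine consumes random variates in
  exactly the same order as the exported R step functions, and the test
  suite asserts trace-identical behavior between the two.
* **Optimization.** The corrected protocol searches
  `alpha_c, alpha_actor ∈ [1e-3, 1]`, `beta ∈ [1e-3, 10]` by Latin-hypercube
  sampling plus Nelder-Mead refinement from the best samples, repeated from
  independent sampling seeds with the across-repeat dispersion reported
  (repeated searches on simulation objectives can land on different
  optima). Evaluations share one base seed (common random numbers). The
  search evaluates 100 simulations per point and headline values are
  re-assessed at larger counts; results are a performance lower bound, not
  a certified global optimum. The legacy protocol is an exhaustive grid
  with `beta` restricted to 1–10; its default levels are illustrative and
  any explicit grid can be supplied.

## Problem sizes used by the test suite

Unit tests run on short horizons (tens to hundreds of trials) and small
simulation counts. The end-to-end checks use the full study conditions:
1000-trial Bernoulli and 2000-trial Gaussian horizons, 500–1000 simulations
per curve, a 250-point legacy grid at 100 simulations per point, and a
bounded search of roughly 500–900 objective evaluations.

## Known limitations and an honest negative result

* The multiplicative actor rule makes weight trajectories sensitive to
  early outcomes; conclusions at small simulation counts are noisy, which
  is why dispersion is always reported.
* Under the update rules exactly as specified here, the 10-arm 0.9/0.8
  Bernoulli task does **not** favor low softmax temperatures: the
  restricted (`beta ≥ 1`) grid's best configuration attains lower mean
  cumulative regret than the `[0.25, 0.25, 0.25]` reference set, and the
  bounded search selects `beta` well above 1. With a fast per-arm critic
  the RPEs center within a few pulls of an arm, after which the Hebbian
  actors accumulate little discriminative signal, and moderately greedy
  high-temperature policies profit from the rule's multiplicative
  lose-shift dynamics. The corresponding acceptance checks are therefore
  expected to flag this discrepancy rather than hide it. The Gaussian
  results — stabilization within 2000 trials, the null effect of removing
  the meta-critic, and the cost of the G-only ablation — all hold.
* Asymmetric actor learning rates, optimization of `k` and `phi`,
  distribution-aware meta-critics, and novelty-based dopamine mechanisms
  are deliberately not implemented.

## A worked example

```{r example, eval = FALSE}
env <- make_bernoulli_env(c(0.9, rep(0.8, 9)))
agent <- opal_agent(opal_params(alpha_c = 0.25, alpha_actor = 0.25,
                                beta = 0.25))
br <- run_benchmark(agent, env, horizon = 1000, n_sims = 500, base_seed = 1)
br
compare_agents(list(br,
                    run_benchmark(uniform_agent(), env, 1000, 500, 1),
                    run_benchmark(oracle_agent(), env, 1000, 500, 1)))
```
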