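# opalbandit

Simulation and benchmarking toolkit for **OpAL\***, an opponent actor-critic
model of striatal dopamine, on synthetic multi-armed bandit tasks. It is
aimed at computational-neuroscience and reinforcement-learning researchers
who want a tested, reproducible implementation of the model's corrected
update rules, its ablations, and the regret-based benchmarking and
parameter-optimization protocols used to compare it against standard bandit
agents.

## The model

A per-arm critic learns from reward prediction errors,

V(a) ← V(a) + α_c · δ,  δ = r − V(a),

while opponent Go/NoGo actor weights (D1/D2 pathways) learn from the same δ
in opposite directions through a multiplicative Hebbian rule with annealed
rates ᾱ = α / (1 + t/T):

G(a) ← G(a) + ᾱ_G · G(a) · δ,  N(a) ← N(a) + ᾱ_N · N(a) · (−δ).

A Beta-distribution meta-critic over the probability of positive RPEs
summarizes reward richness; when its posterior mean m is confidently away
from 0.5 (φ posterior SDs), a dopamine-like gain ρ = clip(k(m − 0.5), −1, 1)
modulates the opponent softmax:

Act(a) = β(1+ρ)·G(a) − β(1−ρ)·N(a),  P(a) = softmax(Act).

Defaults reproduce the corrected model (G/N initialized at 1, no weight cap,
T = 100); an `opal_flaws()` switch reproduces a criticized legacy variant
(init 0.5, cap at 10, T = 10) for side-by-side comparison. Baselines
(softmax Q-learning, UCB, uniform, oracle) and ablations (G-only choice,
meta-critic disabled) share one step interface and one benchmark harness.

## Worked example

```r
library(opalbandit)
env <- make_bernoulli_env(c(0.9, rep(0.8, 9)))   # one 0.9 arm vs nine 0.8
agent <- opal_agent(opal_params(alpha_c = 0.25, alpha_actor = 0.25,
                                beta = 0.25))
br <- run_benchmark(agent, env, horizon = 1000, n_sims = 500, base_seed = 1)
br
#> <benchmark_result> opal_star on bernoulli_10arm: 500 sims x 1000 trials
#>   cumulative regret at horizon: 89.460 [89.363, 89.556]

compare_agents(list(br,
                    run_benchmark(uniform_agent(), env, 1000, 500, 1),
                    run_benchmark(oracle_agent(), env, 1000, 500, 1)))
#>       agent             env horizon cum_regret    ci_lo    ci_hi n_sims
#> 1 opal_star bernoulli_10arm    1000    89.4598 89.36348 89.55612    500
#> 2   uniform bernoulli_10arm    1000    89.9764 89.89109 90.06171    500
#> 3    oracle bernoulli_10arm    1000     0.0000  0.00000  0.00000    500
```

Cumulative regret sums the per-trial gap between the best arm's expected
reward (0.9) and the chosen arm's; a uniform policy pays 0.09 per trial on
this task (≈ 90 over 1000 trials) and an always-best oracle pays 0. On the
overlapping-distribution Gaussian task the model performs far better:

```r
genv <- make_gaussian_env(c(0.8, 0.7), 0.1)
run_benchmark(opal_agent(opal_params(0.01, 0.38, beta = 0.25)),
              genv, horizon = 2000, n_sims = 1000, base_seed = 1)
#> <benchmark_result> opal_star on gaussian_2arm: 1000 sims x 2000 trials
#>   cumulative regret at horizon: 58.094 [57.812, 58.377]
```

(Chance would pay 0.05 per trial here, i.e. 100 over 2000 trials.)

Higher-level entry points: `reproduce()` runs the shipped benchmark
pipelines end-to-end (`bernoulli_benchmark`, `gaussian_benchmark`,
`beta_restriction`), `run_from_config()` drives everything from a YAML/JSON
config, `optimize_opal()` runs the bounded global parameter search and
`legacy_grid_search()` the restricted-temperature grid protocol. A thin CLI
wrapper lives at `inst/cli/opalbandit.R`. See the vignette in `vignettes/`
for the model's assumptions, parameter meanings, and design choices.

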