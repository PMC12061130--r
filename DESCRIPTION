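Package: opalbandit
Title: Opponent Actor-Critic (OpAL*) Agents and Multi-Armed Bandit Regret
    Benchmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation toolkit for the OpAL* opponent actor-critic model of
    striatal dopamine: a critic learning from reward prediction errors, Go/NoGo
    (D1/D2) actor weights updated by a multiplicative Hebbian rule with annealed
    learning rates, a Beta-distribution meta-critic tracking the probability of
    positive prediction errors, and dynamic dopamine modulation of the opponent
    softmax gains. Includes Bernoulli and Gaussian multi-armed bandit
    environments with ground-truth regret, baseline agents (softmax Q-learning,
    UCB, uniform and oracle policies) and ablation switches (G-actor-only,
    meta-critic disabled, legacy implementation flaws), a seeded benchmark
    harness producing mean regret curves with confidence bands, a bounded
    global parameter search alongside a restricted legacy grid search, and
    configuration-driven reporting with figures and manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    ggplot2,
    rlang,
    lhs,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
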