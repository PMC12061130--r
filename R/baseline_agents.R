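#' @title Baseline and ablation agents
#' @description Comparison agents sharing the OpAL* step interface: softmax
#'   Q-learning, UCB with a forced warm start, a uniform-random policy and an
#'   always-best oracle (the two closed-form brackets every learning agent
#'   must fall between), plus the OpAL* ablations (G-only choice, disabled
#'   meta-critic, legacy flaws).
#' @name baseline_agents
NULL

#' Softmax Q-learning agent
#'
#' Per-arm value estimates updated by the delta rule
#' `Q[arm] <- Q[arm] + alpha * (r - Q[arm])`, with choice by softmax over
#' `beta * Q`.
#'
#' @param alpha learning rate in (0, 1].
#' @param beta softmax temperature (> 0).
#' @param q0 initial value estimate for every arm.
#' @param name agent label.
#' @return a `bandit_agent`.
#' @export
q_agent <- function(alpha, beta, q0 = 0, name = "q_softmax") {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1, beta > 0,
            is.numeric(q0), length(q0) == 1, is.finite(q0))
  structure(
    list(name = name, type = "q", native = TRUE,
         native_params = list(alpha = alpha, beta = beta, q0 = q0),
         init = function(env) list(Q = rep(q0, env$n_arms), t = 0L),
         step = function(state, env) q_step(state, env, alpha, beta)),
    class = "bandit_agent")
}

#' One softmax Q-learning trial
#'
#' @param state list with per-arm `Q` and trial counter `t`.
#' @param env a `bandit_env`.
#' @param alpha,beta learning rate and softmax temperature.
#' @return `list(state, record)` in the common step contract.
#' @export
q_step <- function(state, env, alpha, beta) {
  arm <- select_action(beta * state$Q)
  reward <- draw_outcome(env, arm)
  delta <- reward - state$Q[arm]
  state$Q[arm] <- state$Q[arm] + alpha * delta
  state$t <- state$t + 1L
  list(state = state,
       record = list(t = state$t, arm = arm, reward = reward, delta = delta,
                     rho = NA_real_, regret = expected_regret(env, arm)))
}

#' Upper Confidence Bound (UCB) agent
#'
#' Pulls every arm once, in order, then picks the arm maximizing
#' `mean[a] + c * sqrt(2 * log(t) / counts[a])` with ties broken uniformly
#' at random.
#'
#' @param c exploration coefficient (default 1; the value is not pinned down
#'   by the benchmark protocol and is optimizable like any other agent
#'   parameter).
#' @param name agent label.
#' @return a `bandit_agent`.
#' @export
ucb_agent <- function(c = 1, name = "ucb") {
  stopifnot(is.numeric(c), length(c) == 1, is.finite(c), c >= 0)
  structure(
    list(name = name, type = "ucb", native = TRUE,
         native_params = list(c = c),
         init = function(env) list(counts = integer(env$n_arms),
                                   means = numeric(env$n_arms), t = 0L),
         step = function(state, env) ucb_step(state, env, c)),
    class = "bandit_agent")
}

#' One UCB trial
#'
#' @param state list with per-arm `counts`, `means` and trial counter `t`.
#' @param env a `bandit_env`.
#' @param c exploration coefficient.
#' @return `list(state, record)` in the common step contract.
#' @export
ucb_step <- function(state, env, c = 1) {
  n <- env$n_arms
  if (state$t < n) {
    arm <- state$t + 1L
  } else {
    score <- state$means + c * sqrt(2 * log(state$t) / state$counts)
    ties <- which(score == max(score))
    arm <- if (length(ties) == 1) ties else {
      j <- min(floor(runif(1) * length(ties)) + 1, length(ties))
      ties[j]
    }
  }
  reward <- draw_outcome(env, arm)
  delta <- reward - state$means[arm]
  state$counts[arm] <- state$counts[arm] + 1L
  state$means[arm] <- state$means[arm] +
    (reward - state$means[arm]) / state$counts[arm]
  state$t <- state$t + 1L
  list(state = state,
       record = list(t = state$t, arm = arm, reward = reward, delta = delta,
                     rho = NA_real_, regret = expected_regret(env, arm)))
}

#' Uniform-random agent
#'
#' Chooses arms uniformly at random forever; its expected per-trial regret is
#' the arm-average regret in closed form, an upper bracket for any learning
#' agent.
#'
#' @param name agent label.
#' @return a `bandit_agent`.
#' @export
uniform_agent <- function(name = "uniform") {
  structure(
    list(name = name, type = "uniform", native = TRUE, native_params = list(),
         init = function(env) list(t = 0L),
         step = function(state, env) {
           arm <- as.integer(min(floor(runif(1) * env$n_arms) + 1,
                                 env$n_arms))
           reward <- draw_outcome(env, arm)
           state$t <- state$t + 1L
           list(state = state,
                record = list(t = state$t, arm = arm, reward = reward,
                              delta = NA_real_, rho = NA_real_,
                              regret = expected_regret(env, arm)))
         }),
    class = "bandit_agent")
}

#' Always-best oracle agent
#'
#' Pulls the (first) optimal arm on every trial: expected regret exactly 0,
#' the lower bracket for any policy.
#'
#' @param name agent label.
#' @return a `bandit_agent`.
#' @export
oracle_agent <- function(name = "oracle") {
  structure(
    list(name = name, type = "oracle", native = TRUE, native_params = list(),
         init = function(env) list(t = 0L),
         step = function(state, env) {
           arm <- env$optimal_arms[1]
           reward <- draw_outcome(env, arm)
           state$t <- state$t + 1L
           list(state = state,
                record = list(t = state$t, arm = arm, reward = reward,
                              delta = NA_real_, rho = NA_real_,
                              regret = expected_regret(env, arm)))
         }),
    class = "bandit_agent")
}

#' G-only OpAL* ablation
#'
#' Identical to the full agent except that the N pathway is excluded from the
#' choice propensities (`propensity = beta_G * G[a]`). By default N keeps
#' learning — the minimal intervention; `freeze_n = TRUE` additionally stops
#' N from updating.
#'
#' @param params an [opal_params()] object.
#' @param freeze_n also freeze N learning.
#' @return a `bandit_agent`.
#' @export
make_g_only_opal <- function(params, freeze_n = FALSE) {
  opal_agent(params, g_only = TRUE, freeze_n = freeze_n)
}

#' Meta-critic-disabled OpAL* ablation
#'
#' The full agent with `k` forced to 0, so `rho` is identically 0 and both
#' pathways keep the unmodulated gain `beta`.
#'
#' @param params an [opal_params()] object.
#' @return a `bandit_agent`.
#' @export
make_k_zero_opal <- function(params) {
  opal_agent(params, k_zero = TRUE)
}

#' Wrap an external agent implementation
#'
#' Plug-in point for models not shipped with the package (e.g. other neural
#' bandit models): supply `init(env) -> state` and
#' `step(state, env) -> list(state, record)` honouring the common step
#' contract; the record must carry `t`, `arm`, `reward`, `delta`, `rho` and
#' `regret`. External agents run on the R engine.
#'
#' @param init state constructor, a function of the environment.
#' @param step trial function in the common contract.
#' @param name agent label.
#' @return a `bandit_agent` with `native = FALSE`.
#' @export
external_agent <- function(init, step, name = "external") {
  stopifnot(is.function(init), is.function(step))
  structure(list(name = name, type = "external", native = FALSE,
                 init = init, step = step),
            class = "bandit_agent")
}

#' Build an agent from the registry by name
#'
#' Registry keys: `opal_star`, `opal_g_only`, `opal_k0`, `opal_flawed`,
#' `q_softmax`, `ucb`, `uniform`, `oracle`. OpAL variants take an
#' [opal_params()] object (or the arguments to build one) via `params`/`...`;
#' `opal_flawed` turns on all legacy flaws.
#'
#' @param name registry key.
#' @param params an [opal_params()] object for the OpAL variants.
#' @param ... passed to the underlying constructor ([opal_params()] for OpAL
#'   variants when `params` is missing, otherwise e.g. `alpha`, `beta`, `c`).
#' @return a `bandit_agent`.
#' @export
make_agent <- function(name, params = NULL, ...) {
  opal_p <- function() {
    if (!is.null(params)) params else opal_params(...)
  }
  switch(name,
    opal_star = opal_agent(opal_p()),
    opal_g_only = make_g_only_opal(opal_p()),
    opal_k0 = make_k_zero_opal(opal_p()),
    opal_flawed = {
      p <- opal_p()
      p$flaws <- opal_flaws(init_half = TRUE, cap_at_10 = TRUE,
                            T_equals_10 = TRUE)
      opal_agent(p, name = "opal_star_flawed")
    },
    q_softmax = q_agent(...),
    ucb = ucb_agent(...),
    uniform = uniform_agent(),
    oracle = oracle_agent(),
    stop(sprintf("unknown agent '%s'; available: %s", name,
                 paste(c("opal_star", "opal_g_only", "opal_k0", "opal_flawed",
                         "q_softmax", "ucb", "uniform", "oracle"),
                       collapse = ", ")))
  )
}
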