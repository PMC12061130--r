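#' @title The OpAL* opponent actor-critic agent
#' @description A critic learns per-arm values from reward prediction errors
#'   (RPEs). Two opponent actor weight sets — G ("Go", D1 pathway) and N
#'   ("NoGo", D2 pathway) — learn from the same RPEs in opposite directions
#'   through a multiplicative Hebbian rule, so each weight's change is scaled
#'   by its own current magnitude. A Beta-distribution meta-critic tracks the
#'   probability of positive RPEs; when it is confident the environment is
#'   reward-rich (or reward-sparse), a dopamine-like gain `rho` amplifies the
#'   G (or N) pathway's contribution to choice.
#' @name opal_agent
NULL

#' Flags reproducing a criticized legacy implementation
#'
#' The corrected model leaves all three off. Turning them on reproduces,
#' exactly, a flawed variant: G/N weights initialized at 0.5 instead of 1
#' (breaking the first-update reduction to a standard actor rule), actor
#' weights hard-capped at 10, and the annealing constant set to 10 instead
#' of 100.
#'
#' @param init_half initialize G and N at 0.5 instead of 1.
#' @param cap_at_10 clip G and N at 10 after every update.
#' @param T_equals_10 use annealing constant 10 instead of the configured one.
#' @return a named list of logical flags.
#' @export
opal_flaws <- function(init_half = FALSE, cap_at_10 = FALSE,
                       T_equals_10 = FALSE) {
  list(init_half = isTRUE(init_half), cap_at_10 = isTRUE(cap_at_10),
       T_equals_10 = isTRUE(T_equals_10))
}

#' OpAL* parameters
#'
#' @param alpha_c critic learning rate in (0, 1].
#' @param alpha_actor actor learning rate in (0, 1]; convenience setter for
#'   both `alpha_g` and `alpha_n` (the benchmark protocol constrains them to
#'   be equal).
#' @param beta softmax temperature, any strictly positive real — values below
#'   1 are explicitly admissible and matter for tasks with many arms.
#' @param alpha_g,alpha_n per-pathway actor learning rates; default to
#'   `alpha_actor`.
#' @param k dopamine modulation strength, >= 0; `k = 0` disables modulation
#'   entirely (`rho` is identically 0). Default 20.
#' @param phi meta-critic confidence multiplier, >= 0: `rho` is gated to 0
#'   unless the Beta posterior mean is more than `phi` posterior standard
#'   deviations away from 0.5. Default 1.
#' @param T_anneal annealing constant `T > 0`; the effective actor rate at
#'   trial `t` is `alpha / (1 + t/T)`. Default 100.
#' @param v0 critic initialization; `NULL` (default) resolves to 0.5 for
#'   Bernoulli tasks and to the midpoint of the arm means for Gaussian tasks
#'   (e.g. 0.75 for means 0.8 vs 0.7), so early RPEs carry signal about
#'   which arm is better.
#' @param gn0 actor weight initialization, default 1: with `gn0 = 1` the
#'   multiplicative term is the identity and the first actor update reduces
#'   to a standard (non-Hebbian) actor update.
#' @param weight_floor small positive lower bound for G and N; zero is
#'   absorbing under a multiplicative rule and negative weights are
#'   meaningless, so weights are floored here after every update.
#' @param eta0,zeta0 Beta meta-critic prior counts (default 1, 1: uniform
#'   prior, `rho = 0` before any data).
#' @param forced_sampling pull every arm once, in order, before using the
#'   softmax policy (an alternative warm start to informative `v0`).
#' @param flaws see [opal_flaws()].
#' @return an object of class `opal_params`.
#' @export
opal_params <- function(alpha_c, alpha_actor = NULL, beta,
                        alpha_g = alpha_actor, alpha_n = alpha_actor,
                        k = 20, phi = 1, T_anneal = 100,
                        v0 = NULL, gn0 = 1, weight_floor = 1e-6,
                        eta0 = 1, zeta0 = 1, forced_sampling = FALSE,
                        flaws = opal_flaws()) {
  if (is.null(alpha_g) || is.null(alpha_n))
    stop("supply alpha_actor, or both alpha_g and alpha_n")
  chk <- function(x, nm, lo, hi, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        (lo_open && x <= lo) || (!lo_open && x < lo) || x > hi)
      stop(sprintf("%s must be a single number in %s%g, %g]",
                   nm, if (lo_open) "(" else "[", lo, hi))
  }
  chk(alpha_c, "alpha_c", 0, 1, lo_open = TRUE)
  chk(alpha_g, "alpha_g", 0, 1, lo_open = TRUE)
  chk(alpha_n, "alpha_n", 0, 1, lo_open = TRUE)
  chk(beta, "beta", 0, Inf, lo_open = TRUE)
  chk(k, "k", 0, Inf)
  chk(phi, "phi", 0, Inf)
  chk(T_anneal, "T_anneal", 0, Inf, lo_open = TRUE)
  chk(gn0, "gn0", 0, Inf, lo_open = TRUE)
  chk(weight_floor, "weight_floor", 0, Inf, lo_open = TRUE)
  chk(eta0, "eta0", 0, Inf, lo_open = TRUE)
  chk(zeta0, "zeta0", 0, Inf, lo_open = TRUE)
  if (!is.null(v0)) stopifnot(is.numeric(v0), all(is.finite(v0)))
  structure(
    list(alpha_c = alpha_c, alpha_g = alpha_g, alpha_n = alpha_n, beta = beta,
         k = k, phi = phi, T_anneal = T_anneal, v0 = v0, gn0 = gn0,
         weight_floor = weight_floor, eta0 = eta0, zeta0 = zeta0,
         forced_sampling = isTRUE(forced_sampling), flaws = flaws),
    class = "opal_params")
}

# Legacy flaw flags resolved into the constants the update rules use.
opal_effective <- function(params) {
  list(gn0 = if (params$flaws$init_half) 0.5 else params$gn0,
       T_anneal = if (params$flaws$T_equals_10) 10 else params$T_anneal,
       cap = if (params$flaws$cap_at_10) 10 else Inf)
}

resolve_v0 <- function(params, env) {
  if (!is.null(params$v0)) {
    v0 <- params$v0
    if (length(v0) == 1) v0 <- rep(v0, env$n_arms)
    if (length(v0) != env$n_arms) stop("v0 length must be 1 or n_arms")
    return(v0)
  }
  if (env$kind == "bernoulli") rep(0.5, env$n_arms)
  else rep(mean(range(env$params$mu)), env$n_arms)
}

#' Initialize OpAL* state for an environment
#'
#' @param params an [opal_params()] object.
#' @param env a `bandit_env`.
#' @return an `opal_state` list with critic values `V`, actor weights `G` and
#'   `N`, meta-critic counts `eta`/`zeta`, trial counter `t`, and the current
#'   dopamine modulation `rho`.
#' @export
opal_state_init <- function(params, env) {
  eff <- opal_effective(params)
  n <- env$n_arms
  structure(
    list(V = resolve_v0(params, env),
         G = rep(eff$gn0, n), N = rep(eff$gn0, n),
         eta = params$eta0, zeta = params$zeta0,
         t = 0L, rho = 0),
    class = "opal_state")
}

#' Critic delta-rule update
#'
#' Computes the reward prediction error `delta = reward - V[arm]` before the
#' update, then moves the chosen arm's value toward the reward:
#' `V[arm] <- V[arm] + alpha_c * delta`. Other arms are untouched.
#'
#' @param state an `opal_state`.
#' @param arm chosen arm index (1-based).
#' @param reward observed reward.
#' @param params an [opal_params()] object.
#' @return `list(state = updated state, delta = the RPE)`.
#' @export
critic_update <- function(state, arm, reward, params) {
  if (!is.finite(reward)) stop("reward must be finite")
  delta <- reward - state$V[arm]
  state$V[arm] <- state$V[arm] + params$alpha_c * delta
  list(state = state, delta = delta)
}

#' Annealed actor learning rate
#'
#' `alpha / (1 + t/T)`: equals `alpha` at `t = 0`, halves by `t = T`, and
#' decreases hyperbolically thereafter, stabilizing the Hebbian actors.
#'
#' @param alpha base learning rate.
#' @param t completed-trial counter (>= 0).
#' @param T_anneal annealing constant (> 0).
#' @return the effective rate.
#' @export
anneal_rate <- function(alpha, t, T_anneal) {
  alpha / (1 + t / T_anneal)
}

#' Opponent Hebbian actor update
#'
#' With the annealed rates `ag`, `an` at the current trial counter,
#' `G[arm] <- G[arm] + ag * G[arm] * delta` and
#' `N[arm] <- N[arm] + an * N[arm] * (-delta)`: the weight change is scaled
#' by the weight itself (activity-dependent), and the two pathways move in
#' opposite directions. Weights are then floored at `weight_floor`; there is
#' no upper cap unless the `cap_at_10` legacy flaw is on.
#'
#' @inheritParams critic_update
#' @param delta the reward prediction error from [critic_update()].
#' @param freeze_n if `TRUE`, leave N unchanged (ablation variant).
#' @return the updated state.
#' @export
actor_update <- function(state, arm, delta, params, freeze_n = FALSE) {
  if (!is.finite(delta)) stop("delta must be finite")
  eff <- opal_effective(params)
  ann <- 1 + state$t / eff$T_anneal
  state$G[arm] <- state$G[arm] + (params$alpha_g / ann) * state$G[arm] * delta
  if (!freeze_n)
    state$N[arm] <- state$N[arm] + (params$alpha_n / ann) * state$N[arm] * (-delta)
  state$G[arm] <- max(min(state$G[arm], eff$cap), params$weight_floor)
  state$N[arm] <- max(min(state$N[arm], eff$cap), params$weight_floor)
  state
}

#' Meta-critic Beta update
#'
#' Increments the positive count `eta` when the RPE is strictly positive and
#' the negative count `zeta` otherwise (`delta = 0` routes to `zeta`), and
#' advances the completed-trial counter. On Bernoulli tasks with the critic
#' held inside (0, 1), a reward of 1 always yields a positive RPE, so `eta`
#' tracks the raw reward count exactly.
#'
#' @inheritParams actor_update
#' @return the updated state.
#' @export
meta_critic_update <- function(state, delta) {
  if (!is.finite(delta)) stop("delta must be finite")
  if (delta > 0) state$eta <- state$eta + 1 else state$zeta <- state$zeta + 1
  state$t <- state$t + 1L
  state
}

#' Dopamine modulation from the meta-critic
#'
#' Let `m` and `s` be the mean and standard deviation of the
#' `Beta(eta, zeta)` posterior over the probability of a positive RPE. If the
#' interval `[m - phi*s, m + phi*s]` still contains 0.5 the agent withholds
#' modulation (`rho = 0`); otherwise `rho = clip(k * (m - 0.5), -1, 1)`.
#' `k = 0` forces `rho = 0` regardless of the counts. The clip keeps both
#' softmax gains `beta * (1 +/- rho)` non-negative.
#'
#' @inheritParams critic_update
#' @return `rho` in `[-1, 1]`.
#' @export
compute_rho <- function(state, params) {
  if (params$k <= 0) return(0)
  tot <- state$eta + state$zeta
  m <- state$eta / tot
  s <- sqrt(state$eta * state$zeta / (tot^2 * (tot + 1)))
  if (m - params$phi * s > 0.5 || m + params$phi * s < 0.5)
    max(min(params$k * (m - 0.5), 1), -1)
  else 0
}

#' Opponent softmax propensities
#'
#' `beta_G = beta * (1 + rho)` amplifies the G pathway when the environment
#' is reward-rich, `beta_N = beta * (1 - rho)` the N pathway when it is
#' sparse; the propensity of arm `a` is `beta_G * G[a] - beta_N * N[a]`
#' (just `beta_G * G[a]` for the G-only ablation). Uses the `rho` stored in
#' the state, which [opal_step()] refreshes once per trial before choice.
#'
#' @inheritParams critic_update
#' @param g_only drop the N pathway from choice.
#' @return numeric vector of per-arm propensities.
#' @export
action_propensities <- function(state, params, g_only = FALSE) {
  bg <- params$beta * (1 + state$rho)
  bn <- params$beta * (1 - state$rho)
  if (g_only) bg * state$G else bg * state$G - bn * state$N
}

#' Softmax choice probabilities
#'
#' Max-shifted for numerical stability: `exp(x - max(x)) / sum(...)`.
#'
#' @param propensities numeric vector of finite propensities.
#' @return probabilities summing to 1.
#' @export
softmax_probs <- function(propensities) {
  if (any(!is.finite(propensities))) stop("propensities must be finite")
  w <- exp(propensities - max(propensities))
  w / sum(w)
}

#' Sample an arm from softmax propensities
#'
#' Consumes one uniform variate from R's global stream.
#'
#' @inheritParams softmax_probs
#' @return the sampled arm index (1-based).
#' @export
select_action <- function(propensities) {
  p <- softmax_probs(propensities)
  u <- runif(1)
  min(1L + sum(u > cumsum(p)), length(p))
}

#' One full OpAL* trial
#'
#' Composition, in order: refresh `rho` ([compute_rho()]), form propensities
#' ([action_propensities()]), sample an arm ([select_action()]), draw the
#' outcome ([draw_outcome()]), update the critic ([critic_update()]), the
#' actors ([actor_update()]) and the meta-critic ([meta_critic_update()]).
#' When `forced_sampling` is on and fewer trials than arms have elapsed, the
#' arm is the trial index and no selection variate is consumed.
#'
#' @inheritParams critic_update
#' @param env a `bandit_env`.
#' @param g_only,freeze_n ablation switches (see [make_g_only_opal()]).
#' @return `list(state = updated state, record = list(t, arm, reward, delta,
#'   rho, regret))`.
#' @export
opal_step <- function(state, env, params, g_only = FALSE, freeze_n = FALSE) {
  state$rho <- compute_rho(state, params)
  if (params$forced_sampling && state$t < env$n_arms) {
    arm <- state$t + 1L
  } else {
    arm <- select_action(action_propensities(state, params, g_only))
  }
  reward <- draw_outcome(env, arm)
  cu <- critic_update(state, arm, reward, params)
  state <- actor_update(cu$state, arm, cu$delta, params, freeze_n)
  rho_used <- state$rho
  state <- meta_critic_update(state, cu$delta)
  list(state = state,
       record = list(t = state$t, arm = arm, reward = reward,
                     delta = cu$delta, rho = rho_used,
                     regret = expected_regret(env, arm)))
}

#' Construct an OpAL* agent
#'
#' Wraps [opal_params()] into the common agent interface used by
#' [run_episode()] and [run_benchmark()]. Ablations are switches on the same
#' code path, not separate implementations.
#'
#' @param params an [opal_params()] object.
#' @param g_only use only the G actor for choice (N still learns unless
#'   `freeze_n`).
#' @param freeze_n additionally stop N from learning.
#' @param k_zero force `k = 0`, disabling dopamine modulation.
#' @param name agent label; a default is derived from the switches.
#' @return a `bandit_agent` object.
#' @examples
#' ag <- opal_agent(opal_params(alpha_c = 0.25, alpha_actor = 0.25, beta = 0.25))
#' env <- make_bernoulli_env(c(0.9, rep(0.8, 9)))
#' tr <- run_episode(ag, env, horizon = 100, seed = 1)
#' mean(tr$regret)
#' @export
opal_agent <- function(params, g_only = FALSE, k_zero = FALSE,
                       freeze_n = FALSE, name = NULL) {
  stopifnot(inherits(params, "opal_params"))
  if (k_zero) params$k <- 0
  if (is.null(name)) {
    name <- "opal_star"
    if (g_only) name <- paste0(name, "_g_only")
    if (k_zero) name <- paste0(name, "_k0")
    if (any(unlist(params$flaws))) name <- paste0(name, "_flawed")
  }
  structure(
    list(name = name, type = "opal", params = params,
         g_only = isTRUE(g_only), freeze_n = isTRUE(freeze_n), native = TRUE,
         init = function(env) opal_state_init(params, env),
         step = function(state, env) opal_step(state, env, params,
                                               g_only = g_only,
                                               freeze_n = freeze_n)),
    class = "bandit_agent")
}

agent_native_spec <- function(agent, env) {
  if (agent$type == "opal") {
    p <- agent$params
    eff <- opal_effective(p)
    list(type = "opal", alpha_c = p$alpha_c, alpha_g = p$alpha_g,
         alpha_n = p$alpha_n, beta = p$beta, k = p$k, phi = p$phi,
         T_anneal = eff$T_anneal, gn0 = eff$gn0,
         weight_floor = p$weight_floor, cap = eff$cap,
         eta0 = p$eta0, zeta0 = p$zeta0,
         g_only = agent$g_only, freeze_n = agent$freeze_n,
         forced_sampling = p$forced_sampling,
         v0 = resolve_v0(p, env))
  } else {
    c(list(type = agent$type), agent$native_params)
  }
}

#' @export
print.bandit_agent <- function(x, ...) {
  cat(sprintf("<bandit_agent> %s (type %s, %s engine)\n", x$name, x$type,
              if (isTRUE(x$native)) "native" else "R"))
  invisible(x)
}
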