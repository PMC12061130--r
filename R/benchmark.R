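#' @title Seeded regret benchmarks
#' @description Runs many independently seeded episodes of an agent on an
#'   environment and aggregates per-trial expected regret into mean curves
#'   with normal-approximation confidence bands — the quantity the bandit
#'   comparisons are judged on (lower is better).
#' @name benchmark
NULL

#' Run one seeded episode
#'
#' Fully deterministic given the agent parameters, the environment and the
#' seed. Native agents run on a compiled engine by default; `engine = "r"`
#' runs the same trial composition through the exported R step functions and
#' yields an identical trace (a parity the test suite enforces).
#'
#' @param agent a `bandit_agent`.
#' @param env a `bandit_env`.
#' @param horizon number of trials (>= 1).
#' @param seed integer seed for this episode.
#' @param engine `"cpp"` (default, native agents only) or `"r"`.
#' @return an `episode_trace`: per-trial vectors `arm`, `reward`, `delta`,
#'   `rho`, `regret` plus the final agent state and identifying metadata.
#' @export
run_episode <- function(agent, env, horizon, seed,
                        engine = c("cpp", "r")) {
  stopifnot(inherits(agent, "bandit_agent"), inherits(env, "bandit_env"))
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 1 ||
      horizon != round(horizon))
    stop("horizon must be a positive integer")
  horizon <- as.integer(horizon)
  engine <- match.arg(engine)
  if (!isTRUE(agent$native)) engine <- "r"
  set.seed(seed)
  if (engine == "cpp") {
    res <- cpp_run_episode(agent_native_spec(agent, env),
                           env_native_spec(env), horizon)
  } else {
    state <- agent$init(env)
    arm <- integer(horizon); reward <- numeric(horizon)
    delta <- numeric(horizon); rho <- numeric(horizon)
    regret <- numeric(horizon)
    for (i in seq_len(horizon)) {
      st <- agent$step(state, env)
      state <- st$state
      arm[i] <- as.integer(st$record$arm); reward[i] <- st$record$reward
      delta[i] <- st$record$delta; rho[i] <- st$record$rho
      regret[i] <- st$record$regret
    }
    res <- list(arm = arm, reward = reward, delta = delta, rho = rho,
                regret = regret, final_state = state)
  }
  structure(
    list(trial = seq_len(horizon), arm = res$arm, reward = res$reward,
         delta = res$delta, rho = res$rho, regret = res$regret,
         final_state = res$final_state, seed = seed, agent = agent$name,
         env = env$name, horizon = horizon),
    class = "episode_trace")
}

#' Run a full benchmark of one agent on one environment
#'
#' Simulation `i` (1..`n_sims`) runs a fresh agent with seed
#' `base_seed + i`. Because every simulation owns its seed, splitting the
#' work across workers cannot change the result; `n_workers > 1` uses
#' forked workers via the parallel package.
#'
#' @inheritParams run_episode
#' @param n_sims number of independent simulations (>= 1).
#' @param base_seed integer; simulation `i` uses `base_seed + i`.
#' @param n_workers number of parallel workers (default 1, serial).
#' @return a `benchmark_result` with per-trial mean regret and cumulative
#'   mean regret, 95% confidence bands (`mean +/- 1.96 * SD / sqrt(n_sims)`
#'   across simulations), and summary statistics of cumulative regret at the
#'   horizon.
#' @examples
#' env <- make_bernoulli_env(c(0.9, rep(0.8, 9)))
#' br <- run_benchmark(uniform_agent(), env, horizon = 50, n_sims = 20,
#'                     base_seed = 1)
#' br$cum_final$mean
#' @export
run_benchmark <- function(agent, env, horizon, n_sims, base_seed,
                          engine = c("cpp", "r"), n_workers = 1) {
  stopifnot(is.numeric(n_sims), length(n_sims) == 1, n_sims >= 1,
            n_sims == round(n_sims))
  engine <- match.arg(engine)
  one <- function(i) run_episode(agent, env, horizon,
                                 seed = base_seed + i, engine = engine)$regret
  rows <- if (n_workers > 1) {
    parallel::mclapply(seq_len(n_sims), one, mc.cores = n_workers)
  } else {
    lapply(seq_len(n_sims), one)
  }
  R <- do.call(rbind, rows)                      # n_sims x horizon
  Rc <- if (horizon == 1) R else t(apply(R, 1, cumsum))  # cumulative per sim
  z <- 1.96
  mean_regret <- colMeans(R)
  sd_regret <- if (n_sims > 1) apply(R, 2, sd) else rep(0, horizon)
  cum_mean <- colMeans(Rc)
  cum_sd <- if (n_sims > 1) apply(Rc, 2, sd) else rep(0, horizon)
  se <- sd_regret / sqrt(n_sims)
  cum_se <- cum_sd / sqrt(n_sims)
  fin_sd <- if (n_sims > 1) sd(Rc[, horizon]) else 0
  structure(
    list(agent = agent$name, env = env$name, horizon = as.integer(horizon),
         n_sims = as.integer(n_sims), base_seed = base_seed,
         trial = seq_len(horizon),
         mean_regret = mean_regret,
         ci_lo = mean_regret - z * se, ci_hi = mean_regret + z * se,
         cum_regret = cum_mean,
         cum_ci_lo = cum_mean - z * cum_se, cum_ci_hi = cum_mean + z * cum_se,
         cum_final = list(mean = cum_mean[horizon], sd = fin_sd,
                          ci_lo = cum_mean[horizon] - z * fin_sd / sqrt(n_sims),
                          ci_hi = cum_mean[horizon] + z * fin_sd / sqrt(n_sims))),
    class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("<benchmark_result> %s on %s: %d sims x %d trials\n",
              x$agent, x$env, x$n_sims, x$horizon))
  cat(sprintf("  cumulative regret at horizon: %.3f [%.3f, %.3f]\n",
              x$cum_final$mean, x$cum_final$ci_lo, x$cum_final$ci_hi))
  invisible(x)
}

#' Flatten a benchmark result to a per-trial data frame
#'
#' Columns: `agent`, `env`, `trial`, `mean_regret`, `cum_regret`, `ci_lo`,
#' `ci_hi` (band on the per-trial mean).
#'
#' @param x a `benchmark_result`.
#' @param ... unused.
#' @export
as.data.frame.benchmark_result <- function(x, ...) {
  data.frame(agent = x$agent, env = x$env, trial = x$trial,
             mean_regret = x$mean_regret, cum_regret = x$cum_regret,
             ci_lo = x$ci_lo, ci_hi = x$ci_hi,
             stringsAsFactors = FALSE)
}

#' Tabulate cumulative regret at the horizon across agents
#'
#' All results must share the environment and horizon; row order follows the
#' input order.
#'
#' @param results a list of `benchmark_result` objects.
#' @return a data frame with one row per agent: cumulative regret at the
#'   horizon, its 95% confidence interval, and `n_sims`.
#' @export
compare_agents <- function(results) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "benchmark_result")))
  envs <- vapply(results, `[[`, "", "env")
  hors <- vapply(results, `[[`, 1L, "horizon")
  if (length(unique(envs)) != 1 || length(unique(hors)) != 1)
    stop("results must share one environment and one horizon")
  data.frame(
    agent = vapply(results, `[[`, "", "agent"),
    env = envs[1], horizon = hors[1],
    cum_regret = vapply(results, function(r) r$cum_final$mean, 1),
    ci_lo = vapply(results, function(r) r$cum_final$ci_lo, 1),
    ci_hi = vapply(results, function(r) r$cum_final$ci_hi, 1),
    n_sims = vapply(results, `[[`, 1L, "n_sims"),
    stringsAsFactors = FALSE)
}
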