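test_that("parameter validation enforces admissible ranges and defaults", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 0.5)
  expect_equal(p$gn0, 1)
  expect_equal(p$T_anneal, 100)
  expect_equal(p$k, 20)
  expect_error(opal_params(alpha_c = 0, alpha_actor = 0.3, beta = 1), "alpha_c")
  expect_error(opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = -1), "beta")
  expect_error(opal_params(alpha_c = 0.1, beta = 1), "alpha_actor")
  # beta below 1 is explicitly admissible
  expect_silent(opal_params(alpha_c = 0.1, alpha_actor = 0.1, beta = 0.05))
})

test_that("critic update follows the delta rule exactly", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 1)
  st <- opal_state_init(p, ten_arm_env())
  cu <- critic_update(st, 3, 1, p)
  expect_equal(cu$delta, 0.5)
  expect_equal(cu$state$V[3], 0.55)
  expect_equal(cu$state$V[-3], st$V[-3])
  # reward equal to the estimate is a fixed point
  cu2 <- critic_update(st, 1, st$V[1], p)
  expect_equal(cu2$delta, 0)
  expect_identical(cu2$state$V, st$V)
  expect_error(critic_update(st, 1, Inf, p), "finite")
})

test_that("critic converges to the arm mean under repeated stochastic rewards", {
  p <- opal_params(alpha_c = 0.01, alpha_actor = 0.3, beta = 1)
  st <- opal_state_init(p, make_bernoulli_env(c(0.9, 0.5)))
  set.seed(5)
  for (i in 1:5000) {
    r <- as.numeric(runif(1) < 0.9)
    st <- critic_update(st, 1, r, p)$state
  }
  expect_lt(abs(st$V[1] - 0.9), 0.05)
})

test_that("first actor update reduces to the standard actor rule when G=N=1", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 1)
  st <- opal_state_init(p, ten_arm_env())
  st2 <- actor_update(st, 1, 0.2, p)
  expect_equal(st2$G[1], 1 + 0.3 * 0.2, tolerance = 0)
  expect_equal(st2$N[1], 1 + 0.3 * (-0.2), tolerance = 0)
  # magnitude equals annealed-rate times |delta| exactly for arbitrary delta
  d <- -0.47
  st3 <- actor_update(st, 2, d, p)
  expect_equal(abs(st3$G[2] - 1), anneal_rate(0.3, 0, 100) * abs(d))
})

test_that("actor updates are multiplicative, opponent, and hand-unrollable", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.1, beta = 1)
  st <- opal_state_init(p, ten_arm_env())
  st$G[4] <- 2
  # hand-unrolled product: 2 * (1 + 0.1*0.5) * (1 - 0.1*0.5)
  st <- actor_update(st, 4, 0.5, p)
  st <- actor_update(st, 4, -0.5, p)
  expect_equal(st$G[4], 2 * 1.05 * 0.95)
  # delta = 0 leaves weights untouched
  before <- st
  st0 <- actor_update(st, 4, 0, p)
  expect_identical(st0$G, before$G)
  expect_identical(st0$N, before$N)
  # opponency: G and N move in opposite directions whenever delta != 0
  for (d in c(0.3, -0.3, 1.5, -1.5)) {
    s2 <- actor_update(before, 5, d, p)
    expect_true(sign(s2$G[5] - before$G[5]) == -sign(s2$N[5] - before$N[5]))
  }
})

test_that("weights never drop below the floor under randomized delta sequences", {
  set.seed(42)
  env <- ten_arm_env()
  for (rep in 1:20) {
    p <- opal_params(alpha_c = 0.1, alpha_actor = runif(1, 0.1, 1), beta = 1)
    st <- opal_state_init(p, env)
    for (i in 1:200) {
      arm <- sample(10, 1)
      st <- actor_update(st, arm, runif(1, -3, 3), p)
      st <- meta_critic_update(st, runif(1, -1, 1))
    }
    expect_true(all(st$G >= p$weight_floor))
    expect_true(all(st$N >= p$weight_floor))
  }
})

test_that("annealing is hyperbolic in the completed-trial counter", {
  expect_equal(anneal_rate(0.4, 0, 100), 0.4)
  expect_equal(anneal_rate(0.4, 100, 100), 0.2)
  expect_equal(anneal_rate(0.5, 100, 100), 0.25)
  t <- 0:500
  expect_true(all(diff(anneal_rate(0.3, t, 100)) < 0))
})

test_that("meta-critic counts positive RPEs and conserves total count", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 1)
  st <- opal_state_init(p, ten_arm_env())
  st1 <- meta_critic_update(st, 0.3)
  expect_equal(st1$eta, st$eta + 1)
  expect_equal(st1$zeta, st$zeta)
  st2 <- meta_critic_update(st, -0.3)
  expect_equal(st2$zeta, st$zeta + 1)
  # delta = 0 routes to the negative count
  st3 <- meta_critic_update(st, 0)
  expect_equal(st3$zeta, st$zeta + 1)
  # conservation: eta + zeta - priors equals trials elapsed
  set.seed(1)
  stc <- st
  for (i in 1:137) stc <- meta_critic_update(stc, runif(1, -1, 1))
  expect_equal(stc$eta + stc$zeta - (st$eta + st$zeta), 137)
  expect_equal(stc$t, 137L)
})

test_that("rho follows the gated, clipped Beta-moment rule", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 1, k = 20, phi = 1)
  st <- opal_state_init(p, ten_arm_env())
  # symmetric counts: mean 0.5, no modulation at any magnitude
  for (m in c(1, 10, 1000)) {
    st$eta <- m; st$zeta <- m
    expect_equal(compute_rho(st, p), 0)
  }
  # k = 0 disables modulation regardless of counts
  p0 <- p; p0$k <- 0
  st$eta <- 500; st$zeta <- 1
  expect_equal(compute_rho(st, p0), 0)
  # hand-evaluated Beta-moment case: eta=90, zeta=10
  st$eta <- 90; st$zeta <- 10
  s <- sqrt(90 * 10 / (100^2 * 101))
  expect_equal(s, 0.0299, tolerance = 1e-2)
  expect_equal(compute_rho(st, p), 1)
  # uncertain counts whose interval still contains 0.5 stay gated at 0
  st$eta <- 3; st$zeta <- 2
  expect_equal(compute_rho(st, p), 0)
})

test_that("rho modulates the opponent gains as beta_G/beta_N", {
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 0.7)
  st <- opal_state_init(p, ten_arm_env())
  st$rho <- 0
  expect_equal(action_propensities(st, p), rep(0, 10))  # G = N everywhere
  st$G <- runif(10, 0.5, 2); st$N <- runif(10, 0.5, 2)
  st$rho <- 1
  expect_equal(action_propensities(st, p), 2 * 0.7 * st$G)
  st$rho <- -1
  expect_equal(action_propensities(st, p), -2 * 0.7 * st$N)
  # G-only ablation ignores N entirely
  st$rho <- 0.3
  pr1 <- action_propensities(st, p, g_only = TRUE)
  st$N <- st$N * 10
  expect_identical(action_propensities(st, p, g_only = TRUE), pr1)
})

test_that("softmax selection is normalized, closed-form, and frequency-correct", {
  expect_equal(softmax_probs(rep(1.3, 4)), rep(0.25, 4))
  expect_equal(sum(softmax_probs(rnorm(7))), 1)
  expect_equal(softmax_probs(c(10, 0))[1], 1 / (1 + exp(-10)))
  # large propensities do not overflow thanks to the max shift
  expect_equal(sum(softmax_probs(c(1e4, 1e4 - 2))), 1)
  expect_error(select_action(c(1, NaN)), "finite")
  # seeded sampling frequencies match probabilities within 4 sigma
  x <- log(c(0.7, 0.3))
  set.seed(123)
  draws <- replicate(1e5, select_action(x))
  f <- mean(draws == 1)
  expect_lt(abs(f - 0.7), 4 * sqrt(0.7 * 0.3 / 1e5))
})

test_that("one opal step composes the operations in order", {
  env <- make_bernoulli_env(c(1.0, 0.0))
  p <- opal_params(alpha_c = 0.1, alpha_actor = 0.3, beta = 1)
  st <- opal_state_init(p, env)
  set.seed(17)
  out <- opal_step(st, env, p)
  expect_equal(out$state$t, 1L)
  expect_named(out$record, c("t", "arm", "reward", "delta", "rho", "regret"))
  expect_equal(out$record$rho, 0)  # uniform prior, first trial
  # chosen arm determines reward deterministically in this environment
  expect_equal(out$record$reward, c(1, 0)[out$record$arm])
})

test_that("binomial equivalence: eta tracks the reward count trial-for-trial", {
  env <- make_bernoulli_env(c(0.9, 0.8))
  p <- opal_params(alpha_c = 0.05, alpha_actor = 0.1, beta = 1)
  st <- opal_state_init(p, env)
  set.seed(31)
  rewards <- 0
  for (i in 1:1000) {
    out <- opal_step(st, env, p)
    st <- out$state
    rewards <- rewards + out$record$reward
    expect_true(all(st$V > 0 & st$V < 1))
    expect_equal(st$eta - p$eta0, rewards)
  }
})

test_that("legacy flaw flags change trajectories on the same seed", {
  env <- ten_arm_env()
  clean <- opal_agent(demo_params())
  flawed <- make_agent("opal_flawed", params = demo_params())
  t1 <- run_episode(clean, env, 300, seed = 4)
  t2 <- run_episode(flawed, env, 300, seed = 4)
  expect_false(identical(t1$arm, t2$arm) && identical(t1$delta, t2$delta))
  # the flawed variant starts at 0.5 and respects the cap
  expect_true(all(t2$final_state$G <= 10 + 1e-12))
})

test_that("flawed initialization breaks the first-update reduction", {
  p <- demo_params(flaws = opal_flaws(init_half = TRUE))
  st <- opal_state_init(p, ten_arm_env())
  expect_equal(st$G, rep(0.5, 10))
  st2 <- actor_update(st, 1, 0.2, p)
  expect_false(isTRUE(all.equal(st2$G[1] - st$G[1], 0.25 * 0.2)))
})

test_that("actors specialize on the tails of Gaussian outcome distributions", {
  env <- gauss_env()
  ag <- opal_agent(gauss_params())
  g_gap <- n_gap <- numeric(30)
  for (s in seq_len(30)) {
    fs <- run_episode(ag, env, 2000, seed = 100 + s)$final_state
    g_gap[s] <- fs$G[1] - fs$G[2]   # G favors the better arm
    n_gap[s] <- fs$N[2] - fs$N[1]   # N opposes the worse arm
  }
  expect_gt(mean(g_gap), 0)
  expect_gt(mean(n_gap), 0)
})
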