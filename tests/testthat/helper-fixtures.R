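# Shared fixtures built in code at test time.

ten_arm_env <- function() make_bernoulli_env(c(0.9, rep(0.8, 9)))

gauss_env <- function() make_gaussian_env(c(0.8, 0.7), 0.1)

# The Gaussian benchmark parameter set (critic lr, actor lr, softmax beta).
gauss_params <- function(...) {
  opal_params(alpha_c = 0.01, alpha_actor = 0.38, beta = 0.25, ...)
}

demo_params <- function(...) {
  opal_params(alpha_c = 0.25, alpha_actor = 0.25, beta = 0.25, ...)
}

trace_fields <- function(tr) tr[c("arm", "reward", "delta", "rho", "regret")]
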