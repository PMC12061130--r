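minimal_config <- function(out = NULL) {
  list(environment = list(kind = "bernoulli", probabilities = c(0.9, 0.5),
                          name = "tiny"),
       agents = list(list(type = "opal_star", alpha_c = 0.1,
                          alpha_actor = 0.3, beta = 1),
                     list(type = "q_softmax", alpha = 0.2, beta = 2)),
       horizon = 10, n_sims = 2, base_seed = 1, plot = FALSE,
       output = out)
}

test_that("config validation names missing and unknown keys", {
  cfg <- minimal_config()
  expect_silent(validate_run_config(cfg))
  bad <- cfg; bad$horizon <- NULL; bad$frobnicate <- 1
  err <- tryCatch(validate_run_config(bad), error = conditionMessage)
  expect_match(err, "horizon")
  expect_match(err, "frobnicate")
})

test_that("a minimal config run completes with all outputs present", {
  out <- file.path(tempdir(), "opal_min_run")
  unlink(out, recursive = TRUE)
  res <- run_from_config(minimal_config(), out_dir = out)
  expect_true(file.exists(file.path(out, "results.csv")))
  expect_true(file.exists(file.path(out, "comparison.csv")))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(nrow(res$comparison), 2)
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_equal(man$config$horizon, 10)
})

test_that("rerunning the same config reproduces identical numeric results", {
  out1 <- file.path(tempdir(), "opal_rep1")
  out2 <- file.path(tempdir(), "opal_rep2")
  unlink(c(out1, out2), recursive = TRUE)
  run_from_config(minimal_config(), out_dir = out1)
  run_from_config(minimal_config(), out_dir = out2)
  expect_identical(read.csv(file.path(out1, "results.csv")),
                   read.csv(file.path(out2, "results.csv")))
})

test_that("configs round-trip through YAML and JSON files", {
  cfg <- minimal_config()
  yml <- file.path(tempdir(), "cfg.yaml")
  yaml::write_yaml(cfg, yml)
  expect_equal(read_run_config(yml)$horizon, 10)
  jsn <- file.path(tempdir(), "cfg.json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE, null = "null")
  expect_equal(read_run_config(jsn)$horizon, 10)
})

test_that("environment presets resolve by name and unknown names list options", {
  cfg <- minimal_config()
  cfg$environment <- "gaussian_base"
  out <- file.path(tempdir(), "opal_preset_run")
  unlink(out, recursive = TRUE)
  res <- run_from_config(cfg, out_dir = out)
  expect_equal(res$comparison$env[1], "gaussian_base")
  cfg$environment <- "no_such_env"
  expect_error(run_from_config(cfg, out_dir = out), "bernoulli_10arm")
})

test_that("preset listings cover environments, parameters, agents and targets", {
  lp <- list_presets()
  expect_true("bernoulli_10arm" %in% lp$environments)
  expect_true(all(c("gaussian", "beta_demo") %in% lp$opal_params))
  expect_true("opal_star" %in% lp$agents)
  expect_setequal(lp$reproduce, c("bernoulli_benchmark", "gaussian_benchmark",
                                  "beta_restriction"))
  tri <- opal_presets()
  expect_equal(unname(tri$gaussian), c(0.01, 0.38, 0.25))
  expect_equal(unname(tri$bernoulli_1), c(0.01, 0.01, 0.5))
})

test_that("reproduce targets run end-to-end in smoke mode", {
  out <- file.path(tempdir(), "opal_smoke_gauss")
  unlink(out, recursive = TRUE)
  res <- reproduce("gaussian_benchmark", out_dir = out, n_sims = 5,
                   horizon = 40, base_seed = 1)
  expect_length(res$results, 3)
  expect_true(file.exists(file.path(out, "results.csv")))
  out2 <- file.path(tempdir(), "opal_smoke_beta")
  unlink(out2, recursive = TRUE)
  res2 <- reproduce("beta_restriction", out_dir = out2, n_sims = 4,
                    horizon = 30, base_seed = 1, grid_n_sims = 2)
  expect_length(res2$results, 2)
  expect_true(file.exists(file.path(out2, "comparison.csv")))
  expect_error(reproduce("fig9"), "should be one of")
})

test_that("benchmark plots build without error", {
  env <- gauss_env()
  r <- run_benchmark(uniform_agent(), env, 30, 5, base_seed = 1)
  p <- plot_benchmark(list(r))
  expect_s3_class(p, "ggplot")
  p2 <- plot_benchmark(r, cumulative = TRUE)
  expect_s3_class(p2, "ggplot")
})
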