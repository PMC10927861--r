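test_that("the generator is deterministic given a seed", {
  cfg <- simulation_config(seed = 101)
  a <- simulate_ensemble(cfg)
  b <- simulate_ensemble(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$true$theta, b$true$theta)
  # byte-identical CSV across runs
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_comparisons(a$records, p1)
  write_comparisons(simulate_ensemble(cfg)$records, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the draw
  expect_false(identical(
    simulate_ensemble(simulation_config(seed = 102))$records$mean_t,
    a$records$mean_t))
})

test_that("the noiseless limit concentrates every g at mu", {
  sim <- simulate_ensemble(simulation_config(
    k = 40, mu = 0.33, tau2 = 0, n_range = c(1000L, 1000L), seed = 103))
  g <- compute_effects(sim$records)$g
  expect_lt(abs(mean(g) - 0.33), 0.02)
  expect_true(all(abs(g - 0.33) < 0.25))
})

test_that("generated records are valid and carry the configured world", {
  cfg <- simulation_config(k = 120, seed = 104, outcome = "FI")
  sim <- simulate_ensemble(cfg)
  expect_length(validate_records(sim$records), 0)
  expect_equal(nrow(sim$records), 120)
  expect_true(all(sim$records$outcome == "FI"))
  expect_true(all(sim$records$n_c >= cfg$n_range[1] &
                  sim$records$n_t <= cfg$n_range[2]))
  expect_length(sim$true$theta, 120)
  # SE-style rows are consistent with their SDs
  has_se <- !is.na(sim$records$se_c)
  expect_gt(sum(has_se), 0)
  expect_equal(sim$records$se_c[has_se],
               sd_to_se(sim$records$sd_c[has_se], sim$records$n_c[has_se]))
})

test_that("empirical var(g) approaches the analytic variance", {
  # tau2 = 0, equal arms: var of computed g should match the formula
  sim <- simulate_ensemble(simulation_config(
    k = 10000, mu = 0.33, tau2 = 0, n_range = c(8L, 8L), seed = 105))
  eff <- compute_effects(sim$records)
  expect_lt(abs(var(eff$g) - mean(eff$var)), 0.1 * mean(eff$var))
})

test_that("the pipeline recovers the generating parameters end to end", {
  est <- vapply(1:5, function(s) {
    sim <- simulate_ensemble(simulation_config(
      k = 300, mu = 0.33, tau2 = 0.1, seed = s))
    re <- random_effects_pool(compute_effects(sim$records))
    c(re$pooled$estimate, re$heterogeneity$tau2)
  }, numeric(2))
  expect_lt(abs(mean(est[1, ]) - 0.33), 0.05)
  expect_lt(abs(mean(est[2, ]) - 0.1), 0.05)
})

test_that("the default world sits in the stated heterogeneity band", {
  i2 <- vapply(1:5, function(s) {
    sim <- simulate_ensemble(simulation_config(seed = 200 + s))
    heterogeneity(compute_effects(sim$records))$I2
  }, numeric(1))
  expect_gt(mean(i2), 60)
  expect_lt(mean(i2), 90)
})

test_that("shared-control mode triggers the pooling warning on re-read", {
  sim <- simulate_ensemble(simulation_config(
    k = 40, seed = 106, shared_control = TRUE, se_only_frac = 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparisons(sim$records, path)
  expect_warning(read_comparisons(path), "share a control arm")
})

test_that("the fixture table spans the moderator space", {
  fx <- make_fixture_table()
  expect_equal(nrow(fx), 12)
  expect_length(validate_records(fx), 0)
  expect_setequal(as.character(unique(fx$dose_bin)),
                  c("LOW", "MID", "HIGH"))
  expect_setequal(as.character(unique(fx$phase_bin)),
                  c("starter", "finisher", "overall"))
  expect_equal(length(unique(fx$strain)), 3)
  expect_equal(length(unique(fx$leaf_type)), 4)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(tau2 = -1), "tau2")
  expect_error(simulation_config(n_range = c(1, 5)), "n_range")
  expect_error(simulation_config(outcome = "weight"), "outcome")
  expect_error(simulation_config(
    level_probabilities = list(strain = c("Arbor Acres" = 0.5))), "sum to 1")
  expect_error(simulation_config(
    moderator_effects = list(breed = c(x = 1))), "unknown moderator")
})

test_that("true parameters round-trip through the key-value file", {
  sim <- simulate_ensemble(simulation_config(k = 10, seed = 107))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_true_params(sim$true, path)
  kv <- read.delim(path, header = FALSE, col.names = c("key", "value"))
  expect_equal(as.numeric(kv$value[kv$key == "mu"]), sim$true$mu)
  expect_equal(as.numeric(kv$value[kv$key == "tau2"]), sim$true$tau2)
})
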