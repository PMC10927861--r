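test_that("fixed-effect pooling matches the summation oracle", {
  # identical studies
  k <- 7
  eff <- data.frame(g = rep(0.5, k), var = rep(0.1, k))
  p <- fixed_effect_pool(eff)
  expect_equal(p$estimate, 0.5)
  expect_equal(p$se, sqrt(0.1 / k))
  # equal-weight average
  p2 <- fixed_effect_pool(data.frame(g = c(0, 1), var = c(1, 1)))
  expect_equal(p2$estimate, 0.5)
  # unequal variances against the brute-force oracle
  set.seed(3)
  for (i in 1:20) {
    e <- random_effects(sample(3:12, 1))
    expect_equal(fixed_effect_pool(e)$estimate,
                 oracle_weighted_mean(e$g, e$var), tolerance = 1e-12)
  }
  expect_error(fixed_effect_pool(data.frame(g = numeric(0),
                                            var = numeric(0))), "empty")
})

test_that("DerSimonian-Laird tau2 matches hand arithmetic and truncates", {
  # two-study case: Q = 2, df = 1, sum(w) = 2, sum(w^2)/sum(w) = 1
  expect_equal(dl_tau2(data.frame(g = c(0, 2), var = c(1, 1))), 1)
  # homogeneous effects sit in the Q <= df region
  expect_equal(dl_tau2(data.frame(g = rep(0.3, 6),
                                  var = runif(6, 0.1, 0.4))), 0)
  expect_error(dl_tau2(data.frame(g = 1, var = 1)), "k >= 2")
})

test_that("DL tau2 recovers a known between-study variance", {
  # tiny within-study variance, tau2 = 0.25, k = 500
  set.seed(99)
  v <- rep(0.001, 500)
  g <- rnorm(500, 0.2, sqrt(0.25 + v))
  expect_lt(abs(dl_tau2(data.frame(g = g, var = v)) - 0.25), 0.03)
})

test_that("random-effects pool reduces to fixed and widens under heterogeneity", {
  # tau2-hat = 0: identical to fixed-effect
  eff0 <- data.frame(g = rep(0.4, 5), var = c(0.1, 0.2, 0.15, 0.3, 0.12))
  re <- random_effects_pool(eff0)
  fe <- fixed_effect_pool(eff0)
  expect_equal(re$heterogeneity$tau2, 0)
  expect_equal(re$pooled$estimate, fe$estimate)
  expect_equal(re$pooled$se, fe$se)
  # heterogeneous input: CI at least as wide
  set.seed(5)
  for (i in 1:20) {
    e <- random_effects(10, g_sd = 1.5)
    rw <- random_effects_pool(e)$pooled
    fw <- fixed_effect_pool(e)
    expect_gte(rw$ci_high - rw$ci_low, fw$ci_high - fw$ci_low)
  }
  expect_error(random_effects_pool(data.frame(g = 1, var = 1)), "k >= 2")
})

test_that("REML tau2 variant is sane and close to DL on behaved input", {
  set.seed(17)
  e <- data.frame(g = rnorm(80, 0.3, sqrt(0.2 + 0.1)), var = rep(0.1, 80))
  re_dl <- random_effects_pool(e, tau2_method = "DL")
  re_reml <- random_effects_pool(e, tau2_method = "REML")
  expect_gte(re_reml$heterogeneity$tau2, 0)
  expect_equal(re_reml$heterogeneity$tau2, re_dl$heterogeneity$tau2,
               tolerance = 0.1)
})

test_that("heterogeneity statistics satisfy their definitions", {
  set.seed(7)
  e <- random_effects(12, g_sd = 1)
  h <- heterogeneity(e)
  w <- 1 / e$var
  est <- sum(w * e$g) / sum(w)
  expect_equal(h$Q, sum(w * (e$g - est)^2))
  expect_equal(h$df, 11)
  expect_equal(h$p_Q, pchisq(h$Q, 11, lower.tail = FALSE))
  expect_equal(h$I2, i2_from_q(h$Q, 12))
  # Q = df boundary -> I2 = 0
  expect_equal(i2_from_q(11, 12), 0)
  expect_equal(i2_from_q(0, 5), 0)
  # rescaling the whole problem (g by sqrt(c), var by c) leaves Q and I2
  # unchanged; rescaling variances alone changes both
  e2 <- data.frame(g = e$g * sqrt(3), var = e$var * 3)
  expect_equal(heterogeneity(e2)$Q, h$Q, tolerance = 1e-9)
  expect_equal(heterogeneity(e2)$I2, h$I2, tolerance = 1e-9)
  e3 <- data.frame(g = e$g, var = e$var * 3)
  expect_false(isTRUE(all.equal(heterogeneity(e3)$Q, h$Q)))
})

test_that("pooled estimates respect convexity and permutation invariance", {
  set.seed(21)
  for (i in 1:20) {
    e <- random_effects(sample(2:15, 1), g_sd = 1.2)
    re <- random_effects_pool(e)
    expect_gte(re$pooled$estimate, min(e$g))
    expect_lte(re$pooled$estimate, max(e$g))
    perm <- e[sample(nrow(e)), ]
    rp <- random_effects_pool(perm)
    expect_equal(rp$pooled$estimate, re$pooled$estimate, tolerance = 1e-12)
    expect_equal(rp$heterogeneity$Q, re$heterogeneity$Q, tolerance = 1e-12)
  }
})

test_that("subgroup analysis pools each level with its own tau2", {
  sim <- simulate_ensemble(simulation_config(
    k = 240, mu = 0.3, tau2 = 0.1, seed = 31,
    moderator_effects = list(dose_bin = c(MID = -0.3))))
  tab <- subgroup_analysis(sim$records, "dose_bin", "ADG")
  expect_s3_class(tab, "ftlm_subgroup")
  expect_equal(sum(tab$k), nrow(sim$records))
  lo <- tab[tab$level == "LOW", ]
  mid <- tab[tab$level == "MID", ]
  # LOW-level true mean 0.3, MID-level 0.0: ordering and CI recovery
  expect_gt(lo$estimate, mid$estimate)
  expect_true(lo$ci_low <= 0.3 && 0.3 <= lo$ci_high)
  expect_true(mid$ci_low <= 0.0 && 0.0 <= mid$ci_high)
  # all records in one level reproduce the overall pool
  one <- subgroup_analysis(sim$records, "strain", "ADG")
  aa <- one[one$level == "Arbor Acres", ]
  sub <- sim$records[sim$records$strain == "Arbor Acres", ]
  ref <- random_effects_pool(compute_effects(sub))
  expect_equal(aa$estimate, ref$pooled$estimate)
  expect_equal(aa$tau2, ref$heterogeneity$tau2)
  expect_error(subgroup_analysis(sim$records, "bogus", "ADG"),
               "unknown moderator")
})

test_that("levels with a single comparison report their own effect", {
  rec <- make_fixture_table()
  tab <- subgroup_analysis(rec, "dose_bin", "ADG")  # ADG doses: MID 1, HIGH 2
  singles <- tab[tab$k == 1, ]
  expect_gt(nrow(singles), 0)
  expect_true(all(is.na(singles$I2)))
  expect_true(all(singles$ci_low <= singles$estimate &
                  singles$estimate <= singles$ci_high))
})

test_that("fixed-effect Q decomposes exactly over any split", {
  set.seed(13)
  for (i in 1:25) {
    e <- random_effects(sample(6:30, 1), g_sd = 1)
    grp <- sample(letters[1:3], nrow(e), TRUE)
    qp <- q_partition(e, grp)
    expect_equal(qp$Q_total, sum(qp$Q_within) + qp$Q_between,
                 tolerance = 1e-10)
  }
})
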