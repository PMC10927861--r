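# independent oracles and random-case generators shared across tests

# brute-force inverse-variance weighted mean, written as plain summation
oracle_weighted_mean <- function(g, var) {
  num <- 0; den <- 0
  for (i in seq_along(g)) {
    num <- num + g[i] / var[i]
    den <- den + 1 / var[i]
  }
  num / den
}

# two-sided p of the fixed-effect combined z after appending m null studies
# at the mean weight
oracle_combined_p <- function(g, var, m = 0) {
  w <- 1 / var
  wbar <- mean(w)
  z <- sum(w * g) / sqrt(sum(w) + m * wbar)
  2 * pnorm(-abs(z))
}

# smallest m such that the combined p reaches alpha, found by stepping
oracle_fsn_bruteforce <- function(g, var, alpha = 0.05, max_m = 1e6) {
  if (oracle_combined_p(g, var, 0) >= alpha) return(0L)
  m <- 0L
  while (m <= max_m) {
    m <- m + 1L
    if (oracle_combined_p(g, var, m) >= alpha) return(m)
  }
  stop("brute-force FSN exceeded max_m")
}

# random effect set with positive variances
random_effects <- function(k, g_sd = 1, v_range = c(0.05, 0.5)) {
  data.frame(g = rnorm(k, 0, g_sd),
             var = runif(k, v_range[1], v_range[2]))
}

# random two-arm summary inputs for effect-size property tests
random_arms <- function(n) {
  data.frame(
    mean_t = runif(n, -50, 150), sd_t = runif(n, 0.1, 20),
    n_t = sample(2:40, n, TRUE),
    mean_c = runif(n, -50, 150), sd_c = runif(n, 0.1, 20),
    n_c = sample(2:40, n, TRUE))
}
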