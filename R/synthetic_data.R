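#' Configuration for the synthetic trial-ensemble generator
#'
#' Describes the world the generator emulates: k two-arm comparisons whose
#' true standardized effects are drawn from a normal random-effects
#' distribution with grand mean `mu` and between-study variance `tau2`,
#' shifted additively by study-level moderators, and observed through the
#' sampling noise the meta-analytic variance formula assumes.
#'
#' Defaults mirror the composition of the pooled trial base: mostly Arbor
#' Acres broilers fed fermented G. biloba leaf meal at low doses, arm
#' replicate counts of 6-12, `mu = 0.33` (the magnitude of a typical
#' growth-performance pooled effect) and `tau2 = 0.6`, which at these arm
#' sizes puts simulated inconsistency in the 60-90 percent band typical of
#' the subgroup tables.
#'
#' @param k Number of comparisons.
#' @param mu Grand true standardized mean difference.
#' @param tau2 Between-study variance of true effects (>= 0).
#' @param moderator_effects Named list, one entry per moderator, each a
#'   named numeric vector of additive true-effect shifts per level, e.g.
#'   `list(strain = c("Lohmann" = -0.5))`. Unlisted levels shift by 0.
#' @param level_probabilities Named list of per-moderator categorical
#'   distributions (named numeric vectors summing to 1) for `strain`,
#'   `leaf_type` and `microbes`; missing entries use the defaults.
#' @param n_range Integer range (length 2) of per-arm replicate counts,
#'   within \[2, 1000\].
#' @param control_mean,control_sd Scale of the control arm in the outcome's
#'   native unit.
#' @param outcome Outcome code stamped on every generated row.
#' @param se_only_frac Fraction of rows that also carry the SE (exercises
#'   the SE path of the dialect).
#' @param shared_control If `TRUE`, comparisons within a study share one
#'   control arm (multi-dose trials), exercising the shared-control
#'   warning.
#' @param seed Integer root seed; all draw sites derive sub-streams from
#'   it, so runs are reproducible and adding draw sites later does not
#'   shift existing ones.
#' @return A `ftlm_sim_config` list.
#' @export
simulation_config <- function(k = 200, mu = 0.33, tau2 = 0.6,
                              moderator_effects = list(),
                              level_probabilities = list(),
                              n_range = c(6L, 12L),
                              control_mean = 100, control_sd = 10,
                              outcome = "ADG",
                              se_only_frac = 0.25,
                              shared_control = FALSE,
                              seed = 1L) {
  defaults <- list(
    strain = c("Arbor Acres" = 0.8, "Yellow feathered" = 0.1,
               "Lohmann" = 0.1),
    leaf_type = c("G. biloba" = 0.7, "M. alba" = 0.1,
                  "S. androgynus" = 0.1, "C. album" = 0.1),
    microbes = c("A. niger" = 0.32, "A. niger + C. utilis" = 0.25,
                 "T. harzianum" = 0.09,
                 "B. subtilis + Lactobacillus + Saccharomycetes" = 0.10,
                 "B. subtilis + L. plantarum + S. cerevisiae" = 0.10,
                 "B. subtilis" = 0.05, "B. licheniform" = 0.04,
                 "C. utilis" = 0.05))
  lp <- utils::modifyList(defaults, level_probabilities)
  cfg <- list(k = as.integer(k), mu = mu, tau2 = tau2,
              moderator_effects = moderator_effects,
              level_probabilities = lp,
              n_range = as.integer(n_range),
              control_mean = control_mean, control_sd = control_sd,
              outcome = outcome, se_only_frac = se_only_frac,
              shared_control = isTRUE(shared_control),
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "ftlm_sim_config")
}

validate_config <- function(cfg) {
  if (cfg$k < 1) stop("k must be >= 1", call. = FALSE)
  if (cfg$tau2 < 0) stop("tau2 must be >= 0", call. = FALSE)
  if (length(cfg$n_range) != 2 || any(cfg$n_range < 2) ||
      any(cfg$n_range > 1000) || cfg$n_range[1] > cfg$n_range[2])
    stop("n_range must be an increasing pair within [2, 1000]",
         call. = FALSE)
  if (cfg$control_sd <= 0) stop("control_sd must be > 0", call. = FALSE)
  if (!cfg$outcome %in% .OUTCOMES)
    stop("unknown outcome '", cfg$outcome, "'", call. = FALSE)
  for (m in names(cfg$level_probabilities)) {
    p <- cfg$level_probabilities[[m]]
    if (abs(sum(p) - 1) > 1e-8)
      stop("level probabilities for '", m, "' must sum to 1", call. = FALSE)
  }
  bad_mod <- setdiff(names(cfg$moderator_effects), .MODERATORS)
  if (length(bad_mod))
    stop("moderator_effects for unknown moderator(s): ",
         paste(bad_mod, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

# additive true-effect shift for one moderator column
.mod_shift <- function(values, shifts) {
  if (is.null(shifts)) return(rep(0, length(values)))
  out <- shifts[as.character(values)]
  out[is.na(out)] <- 0
  unname(out)
}

# phase windows the trial base uses, with realistic frequencies
.PHASE_WINDOWS <- list(c(1, 21), c(22, 42), c(1, 42), c(1, 56), c(22, 56))
.PHASE_WINDOW_P <- c(0.3, 0.3, 0.25, 0.1, 0.05)

#' Simulate a synthetic ensemble of two-arm feeding comparisons
#'
#' For each comparison: moderators are drawn from the configured
#' categorical distributions; the true effect is
#' \eqn{\theta_i = \mu + \sum shifts + N(0, \tau^2)}; per-arm replicate
#' counts are drawn from `n_range`; the treated true mean is the control
#' mean plus \eqn{\theta_i \sigma}; observed arm means carry
#' \eqn{N(0, \sigma^2/n)} sampling noise and observed arm SDs follow the
#' scaled chi-square law \eqn{s^2 \sim \sigma^2 \chi^2_{n-1}/(n-1)} — the
#' exact sampling structure the effect-size variance formula assumes.
#'
#' Identical seeds give identical output. Each draw site has its own
#' sub-stream derived from the root seed.
#'
#' @param config A `ftlm_sim_config` (see [simulation_config()]).
#' @return List with `records` (a `ftlm_comparisons` data.frame ready for
#'   [compute_effects()]) and `true` (list: `mu`, `tau2`, `theta`,
#'   per-comparison moderator shifts, and the config).
#' @export
simulate_ensemble <- function(config) {
  cfg <- validate_config(config)
  k <- cfg$k
  # derive one sub-seed per draw site from the root seed
  set.seed(cfg$seed)
  site <- sample.int(.Machine$integer.max - 1L, 16L)
  draw <- function(j, expr) { set.seed(site[j]); expr }

  lp <- cfg$level_probabilities
  strain <- draw(1L, sample(names(lp$strain), k, TRUE, lp$strain))
  leaf <- draw(2L, sample(names(lp$leaf_type), k, TRUE, lp$leaf_type))
  microbes <- draw(3L, sample(names(lp$microbes), k, TRUE, lp$microbes))
  dose <- draw(4L, {
    band <- sample(1:3, k, TRUE, c(0.65, 0.2, 0.15))
    lo <- c(0.5, 5, 10)[band]; hi <- c(5, 10, 14)[band]
    round(stats::runif(k, lo, hi), 1)
  })
  win <- draw(5L, sample(length(.PHASE_WINDOWS), k, TRUE, .PHASE_WINDOW_P))
  phase_start <- vapply(.PHASE_WINDOWS[win], `[`, numeric(1), 1)
  phase_end <- vapply(.PHASE_WINDOWS[win], `[`, numeric(1), 2)
  # sample() from the value set, not sample.int, when the range is scalar
  n_pool <- seq.int(cfg$n_range[1], cfg$n_range[2])
  n_c <- draw(6L, n_pool[sample.int(length(n_pool), k, TRUE)])
  n_t <- draw(7L, n_pool[sample.int(length(n_pool), k, TRUE)])

  dose_bin <- assign_dose_bin(dose)
  phase_bin <- assign_phase_bin(phase_start, phase_end)
  shifts <- .mod_shift(strain, cfg$moderator_effects$strain) +
    .mod_shift(leaf, cfg$moderator_effects$leaf_type) +
    .mod_shift(microbes, cfg$moderator_effects$microbes) +
    .mod_shift(dose_bin, cfg$moderator_effects$dose_bin) +
    .mod_shift(phase_bin, cfg$moderator_effects$phase_bin)
  theta <- draw(8L, cfg$mu + shifts + stats::rnorm(k, 0, sqrt(cfg$tau2)))

  # comparisons grouped into synthetic studies of ~8 comparisons
  n_study <- max(2L, as.integer(round(k / 8)))
  study <- sprintf("synth-%03d", rep_len(seq_len(n_study), k))
  sigma <- cfg$control_sd
  mc_true <- draw(9L, cfg$control_mean +
                       stats::rnorm(n_study, 0, 0.05 * abs(cfg$control_mean) +
                                    1e-12)[rep_len(seq_len(n_study), k)])
  mt_true <- mc_true + theta * sigma

  mean_c <- draw(10L, mc_true + stats::rnorm(k, 0, sigma / sqrt(n_c)))
  mean_t <- draw(11L, mt_true + stats::rnorm(k, 0, sigma / sqrt(n_t)))
  sd_c <- draw(12L, sigma * sqrt(stats::rchisq(k, n_c - 1) / (n_c - 1)))
  sd_t <- draw(13L, sigma * sqrt(stats::rchisq(k, n_t - 1) / (n_t - 1)))

  if (cfg$shared_control) {
    # first comparison of each study donates its control arm to the rest
    first <- !duplicated(study)
    idx <- match(study, study[first])
    mean_c <- mean_c[first][idx]
    sd_c <- sd_c[first][idx]
    n_c <- n_c[first][idx]
  }

  se_flag <- draw(14L, stats::runif(k) < cfg$se_only_frac)
  se_c <- ifelse(se_flag, sd_to_se(sd_c, n_c), NA_real_)
  se_t <- ifelse(se_flag, sd_to_se(sd_t, n_t), NA_real_)

  records <- data.frame(
    study_id = study, country = "synthetic", strain = strain,
    leaf_type = leaf, microbes = microbes, dose_g_per_kg = dose,
    phase_start_day = phase_start, phase_end_day = phase_end,
    outcome = cfg$outcome,
    mean_c = mean_c, sd_c = sd_c, se_c = se_c, n_c = as.integer(n_c),
    mean_t = mean_t, sd_t = sd_t, se_t = se_t, n_t = as.integer(n_t),
    stringsAsFactors = FALSE)
  records$dose_bin <- dose_bin
  records$phase_bin <- phase_bin
  class(records) <- c("ftlm_comparisons", "data.frame")

  list(records = records,
       true = list(mu = cfg$mu, tau2 = cfg$tau2, theta = theta,
                   shifts = shifts, config = cfg))
}

#' Deterministic 12-row toy comparison table
#'
#' A hand-written fixture spanning all three strains, all four leaf-meal
#' species, single-organism and mixture fermentations, all three dose bins,
#' all three phase bins, and both the SD and the SE input styles. Used by
#' the unit tests; valid under [validate_records()].
#'
#' @param raw If `TRUE`, return the un-normalized dialect table (SE-only
#'   rows have an empty SD); otherwise the normalized `ftlm_comparisons`.
#' @return A data.frame of 12 comparison rows.
#' @export
make_fixture_table <- function(raw = FALSE) {
  df <- data.frame(
    study_id = sprintf("fix-%02d", 1:12),
    country = c(rep("China", 8), rep("Indonesia", 4)),
    strain = c(rep("Arbor Acres", 6), rep("Yellow feathered", 3),
               rep("Lohmann", 3)),
    leaf_type = c(rep("G. biloba", 6), rep("M. alba", 3),
                  rep("S. androgynus", 2), "C. album"),
    microbes = c("A. niger", "A. niger", "A. niger + C. utilis",
                 "A. niger + C. utilis", "C. utilis", "B. subtilis",
                 rep("B. subtilis + Lactobacillus + Saccharomycetes", 3),
                 "T. harzianum", "T. harzianum",
                 "B. subtilis + L. plantarum + S. cerevisiae"),
    dose_g_per_kg = c(2, 5, 3.5, 8, 10, 12, 2.5, 6, 14, 4, 11, 5.5),
    phase_start_day = c(1, 1, 22, 22, 1, 1, 0, 22, 1, 15, 1, 1),
    phase_end_day = c(21, 21, 42, 42, 42, 56, 21, 56, 42, 35, 56, 42),
    outcome = c(rep("FI", 4), "ADG", "ADG", "FCR", "FCR", "FI", "FI",
                "ADG", "FCR"),
    mean_c = c(95, 96, 160, 158, 52, 55, 1.8, 1.75, 98, 90, 50, 1.7),
    sd_c = c(4, 5, 8, 9, 3, NA, 0.1, 0.12, 6, NA, 4, 0.09),
    se_c = c(NA, NA, NA, NA, NA, 1.2, NA, NA, NA, 1.5, NA, NA),
    n_c = c(8L, 8L, 10L, 10L, 6L, 9L, 8L, 8L, 12L, 6L, 10L, 8L),
    mean_t = c(99, 97, 165, 150, 55, 58, 1.72, 1.70, 96, 88, 48, 1.68),
    sd_t = c(5, 4, 9, 10, 3.2, NA, 0.11, 0.10, 7, NA, 5, 0.08),
    se_t = c(NA, NA, NA, NA, NA, 1.1, NA, NA, NA, 1.4, NA, NA),
    n_t = c(8L, 8L, 10L, 10L, 6L, 9L, 8L, 8L, 12L, 6L, 10L, 8L),
    stringsAsFactors = FALSE)
  if (raw) return(df)
  read_comparisons(df)
}

#' Write generating parameters as a key-value text file
#'
#' @param true The `true` element returned by [simulate_ensemble()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_true_params <- function(true, path) {
  lines <- c(
    sprintf("mu\t%.10g", true$mu),
    sprintf("tau2\t%.10g", true$tau2),
    sprintf("k\t%d", true$config$k),
    sprintf("seed\t%d", true$config$seed),
    sprintf("outcome\t%s", true$config$outcome))
  writeLines(lines, path)
  invisible(path)
}
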