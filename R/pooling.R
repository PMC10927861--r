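# accept either an ftlm_effect data.frame or a list/data.frame with g, var
.as_gv <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("g", "var") %in% names(effects)))
    g <- effects$g; v <- effects$var
  } else if (is.list(effects)) {
    g <- effects$g; v <- effects$var
  } else stop("effects must carry columns g and var", call. = FALSE)
  if (length(g) == 0) stop("empty effect set", call. = FALSE)
  if (any(!is.finite(g)) || any(!is.finite(v)) || any(v <= 0))
    stop("all effects need finite g and var > 0", call. = FALSE)
  list(g = g, v = v, k = length(g))
}

.pooled_result <- function(est, se, k, alpha, model) {
  zc <- stats::qnorm(1 - alpha / 2)
  z <- est / se
  structure(list(
    estimate = est, se = se,
    ci_low = est - zc * se, ci_high = est + zc * se,
    z = z, p = 2 * stats::pnorm(-abs(z)), k = k, model = model,
    alpha = alpha), class = "ftlm_pooled")
}

#' Fixed-effect (inverse-variance) pooling
#'
#' Pools effect sizes with weights \eqn{w_i = 1/var_i}. Mainly a building
#' block: Cochran's Q and the between/within subgroup decomposition are
#' defined on these weights, and the random-effects pool reduces to this in
#' the homogeneous limit.
#'
#' @param effects Effect table with columns `g` and `var` (see
#'   [compute_effects()]), k >= 1.
#' @param alpha Two-sided significance level for the CI (default 0.05).
#' @return An `ftlm_pooled` list: `estimate`, `se`, `ci_low`, `ci_high`,
#'   `z`, `p`, `k`, `model = "fixed"`.
#' @export
fixed_effect_pool <- function(effects, alpha = 0.05) {
  e <- .as_gv(effects)
  w <- 1 / e$v
  est <- sum(w * e$g) / sum(w)
  .pooled_result(est, sqrt(1 / sum(w)), e$k, alpha, "fixed")
}

#' DerSimonian-Laird between-study variance
#'
#' Method-of-moments estimator of the variance of true effects across
#' comparisons:
#' \deqn{\hat\tau^2 = \max\!\left(0,\;
#'   \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right)}
#' with fixed-effect weights \eqn{w_i = 1/var_i} and Cochran's Q.
#'
#' @inheritParams fixed_effect_pool
#' @return Non-negative scalar tau-squared estimate.
#' @export
dl_tau2 <- function(effects) {
  e <- .as_gv(effects)
  if (e$k < 2) stop("tau2 estimation needs k >= 2", call. = FALSE)
  w <- 1 / e$v
  est <- sum(w * e$g) / sum(w)
  Q <- sum(w * (e$g - est)^2)
  max(0, (Q - (e$k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

# REML tau2 by fixed-point iteration of the restricted score equation;
# opt-in alternative to DL
.reml_tau2 <- function(g, v, tol = 1e-10, maxit = 500) {
  t2 <- max(0, stats::var(g) - mean(v))
  for (i in seq_len(maxit)) {
    w <- 1 / (v + t2)
    mu <- sum(w * g) / sum(w)
    t2_new <- max(0, sum(w^2 * ((g - mu)^2 - v)) / sum(w^2) + 1 / sum(w))
    if (abs(t2_new - t2) < tol) return(t2_new)
    t2 <- t2_new
  }
  t2
}

#' Heterogeneity statistics for a set of effects
#'
#' Cochran's Q on fixed-effect weights, its chi-square p-value with k-1
#' degrees of freedom, the inconsistency index
#' \eqn{I^2 = \max(0, 100 (Q - df)/Q)}, and the DerSimonian-Laird
#' tau-squared.
#'
#' @inheritParams fixed_effect_pool
#' @return An `ftlm_heterogeneity` list: `Q`, `df`, `p_Q`, `I2`, `tau2`.
#' @export
heterogeneity <- function(effects) {
  e <- .as_gv(effects)
  if (e$k < 2) stop("heterogeneity needs k >= 2", call. = FALSE)
  w <- 1 / e$v
  est <- sum(w * e$g) / sum(w)
  Q <- sum(w * (e$g - est)^2)
  df <- e$k - 1
  structure(list(
    Q = Q, df = df, p_Q = stats::pchisq(Q, df, lower.tail = FALSE),
    I2 = i2_from_q(Q, e$k), tau2 = dl_tau2(effects)),
    class = "ftlm_heterogeneity")
}

#' Inconsistency index from a Q statistic
#'
#' @param Q Cochran's Q statistic (>= 0).
#' @param k Number of pooled comparisons (df = k - 1).
#' @return I-squared percent in \[0, 100\]: `max(0, 100 * (Q - (k-1)) / Q)`,
#'   0 when Q is 0. Vectorized.
#' @export
i2_from_q <- function(Q, k) {
  stopifnot(Q >= 0, k >= 1)
  ifelse(Q > 0, pmax(0, 100 * (Q - (k - 1)) / Q), 0)
}

#' Random-effects pooling (DerSimonian-Laird)
#'
#' Pools effects under the random-effects model: true effects are assumed
#' drawn from a distribution with mean mu and variance tau-squared, so each
#' comparison is weighted \eqn{w_i^* = 1/(var_i + \hat\tau^2)}. The Wald CI
#' is symmetric (no Knapp-Hartung adjustment). Heterogeneity statistics are
#' computed on fixed-effect weights as usual.
#'
#' @inheritParams fixed_effect_pool
#' @param tau2_method `"DL"` (default, method of moments) or `"REML"`.
#' @return A list with elements `pooled` (`ftlm_pooled`, `model =
#'   "random"`) and `heterogeneity` (`ftlm_heterogeneity`).
#' @export
random_effects_pool <- function(effects, alpha = 0.05, tau2_method = "DL") {
  e <- .as_gv(effects)
  if (e$k < 2) stop("random-effects pooling needs k >= 2", call. = FALSE)
  tau2_method <- match.arg(tau2_method, c("DL", "REML"))
  het <- heterogeneity(effects)
  t2 <- if (tau2_method == "DL") het$tau2 else .reml_tau2(e$g, e$v)
  if (tau2_method == "REML") het$tau2 <- t2
  w <- 1 / (e$v + t2)
  est <- sum(w * e$g) / sum(w)
  pooled <- .pooled_result(est, sqrt(1 / sum(w)), e$k, alpha, "random")
  list(pooled = pooled, heterogeneity = het)
}

#' Restricted subgroup analysis over one moderator
#'
#' Partitions the comparisons for one outcome by the levels of a moderator
#' and pools each level separately under the random-effects model, with
#' tau-squared estimated independently within each level. Levels with a
#' single comparison are reported with that effect's own Wald CI and no
#' heterogeneity statistics.
#'
#' @param records A `ftlm_comparisons` data.frame.
#' @param moderator One of `r paste(ftlm_moderators(), collapse = ", ")`.
#' @param outcome Outcome code to restrict to (see [ftlm_outcomes()]).
#' @param alpha Significance level (default 0.05).
#' @return An `ftlm_subgroup` data.frame, one row per observed level:
#'   `level`, `k`, `estimate`, `ci_low`, `ci_high`, `p`, `I2`, `p_Q`,
#'   `tau2`, `Q`. Attributes `moderator`, `outcome`.
#' @export
subgroup_analysis <- function(records, moderator, outcome, alpha = 0.05) {
  if (!moderator %in% .MODERATORS)
    stop("unknown moderator '", moderator, "'; one of: ",
         paste(.MODERATORS, collapse = ", "), call. = FALSE)
  df <- as.data.frame(records)
  df <- df[df$outcome == outcome, , drop = FALSE]
  if (!nrow(df)) stop("no comparisons for outcome '", outcome, "'",
                      call. = FALSE)
  eff <- compute_effects(df)
  lev <- split(seq_len(nrow(eff)), droplevels(factor(eff[[moderator]])))
  rows <- lapply(names(lev), function(lv) {
    sub <- eff[lev[[lv]], , drop = FALSE]
    if (nrow(sub) >= 2) {
      re <- random_effects_pool(sub, alpha)
      data.frame(level = lv, k = nrow(sub),
                 estimate = re$pooled$estimate,
                 ci_low = re$pooled$ci_low, ci_high = re$pooled$ci_high,
                 p = re$pooled$p, I2 = re$heterogeneity$I2,
                 p_Q = re$heterogeneity$p_Q, tau2 = re$heterogeneity$tau2,
                 Q = re$heterogeneity$Q)
    } else {
      zc <- stats::qnorm(1 - alpha / 2)
      data.frame(level = lv, k = 1L, estimate = sub$g,
                 ci_low = sub$g - zc * sub$se, ci_high = sub$g + zc * sub$se,
                 p = 2 * stats::pnorm(-abs(sub$g / sub$se)),
                 I2 = NA_real_, p_Q = NA_real_, tau2 = NA_real_,
                 Q = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, moderator = moderator, outcome = outcome, alpha = alpha,
            class = c("ftlm_subgroup", "data.frame"))
}

#' Fixed-effect Q decomposition over a subgroup split
#'
#' With common fixed-effect weights, Cochran's Q over all comparisons
#' decomposes exactly into the sum of within-level Q statistics plus a
#' between-level component:
#' \eqn{Q_{total} = \sum_j Q_{within,j} + Q_{between}}.
#'
#' @inheritParams fixed_effect_pool
#' @param groups Factor (or coercible) of the same length as the effect set.
#' @return List with `Q_total`, `Q_within` (named per level), `Q_between`.
#' @export
q_partition <- function(effects, groups) {
  e <- .as_gv(effects)
  groups <- droplevels(factor(groups))
  stopifnot(length(groups) == e$k)
  w <- 1 / e$v
  est_all <- sum(w * e$g) / sum(w)
  Q_total <- sum(w * (e$g - est_all)^2)
  idx <- split(seq_len(e$k), groups)
  Q_within <- vapply(idx, function(i) {
    est_j <- sum(w[i] * e$g[i]) / sum(w[i])
    sum(w[i] * (e$g[i] - est_j)^2)
  }, numeric(1))
  Q_between <- vapply(idx, function(i) {
    est_j <- sum(w[i] * e$g[i]) / sum(w[i])
    sum(w[i]) * (est_j - est_all)^2
  }, numeric(1))
  list(Q_total = Q_total, Q_within = Q_within,
       Q_between = sum(Q_between))
}

#' @export
print.ftlm_pooled <- function(x, ...) {
  cat(sprintf("%s-effects pool: SMD = %.2f [%.2f, %.2f], z = %.2f, %s, k = %d\n",
              x$model, x$estimate, x$ci_low, x$ci_high, x$z,
              format_p(x$p), x$k))
  invisible(x)
}

#' @export
print.ftlm_heterogeneity <- function(x, ...) {
  cat(sprintf("Q = %.2f (df = %d, %s), I2 = %d%%, tau2 = %.3f\n",
              x$Q, x$df, format_p(x$p_Q), round(x$I2), x$tau2))
  invisible(x)
}

#' Format a p-value the way the report tables print it
#'
#' Three decimals with a `P < 0.001` floor.
#'
#' @param p Numeric p-value(s).
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 0.001, "P < 0.001", sprintf("P = %.3f", p))
}
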