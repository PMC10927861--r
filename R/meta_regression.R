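# method-of-moments residual tau2 for a weighted design (DL generalization):
# with W = diag(1/v_i) and hat-complement P = W - W X (X'WX)^{-1} X'W,
# tau2 = max(0, (QE - (k - p)) / tr(P))
.mom_tau2_resid <- function(g, v, X) {
  W <- diag(1 / v, nrow = length(v))
  XtWX <- crossprod(X, W %*% X)
  P <- W - W %*% X %*% solve(XtWX, crossprod(X, W))
  QE <- drop(crossprod(g, P %*% g))
  trP <- sum(diag(P))
  k <- length(g); p <- ncol(X)
  list(tau2 = max(0, (QE - (k - p)) / trP), QE = QE, df_E = k - p)
}

#' Mixed-effects meta-regression on one moderator
#'
#' Regresses effect sizes on a single study-level moderator under the
#' mixed-effects model: residual between-study variance is estimated by
#' the method of moments (the DerSimonian-Laird generalization to a
#' weighted design), then coefficients are fit by weighted least squares
#' with weights \eqn{1/(var_i + \hat\tau^2_{resid})}. The omnibus moderator
#' test QM is a Wald chi-square on all non-intercept coefficients. The
#' share of heterogeneity accounted for is
#' \deqn{R^2 = \max\!\left(0, 100 \left(1 -
#'   \frac{\hat\tau^2_{resid}}{\hat\tau^2_{total}}\right)\right)}
#' with \eqn{\hat\tau^2_{total}} from the intercept-only model, and
#' residual inconsistency is \eqn{I^2_{resid} = \max(0, 100 (Q_E - df_E)/Q_E)}.
#'
#' Categorical moderators are dummy-coded with the alphabetically first
#' observed level as reference; the continuous mode centers the dose.
#'
#' @param records A `ftlm_comparisons` data.frame.
#' @param moderator One of `r paste(ftlm_moderators(), collapse = ", ")`,
#'   or `"dose"` for centered continuous dose.
#' @param outcome Outcome code to restrict to.
#' @param alpha Significance level (default 0.05).
#' @param tau2_method `"MM"` (default, method of moments) or `"REML"`.
#' @return An `ftlm_metareg` list: `moderator`, `outcome`, `k`,
#'   `coefficients` (data.frame: term, estimate, se, z, p), `QM`, `df_M`,
#'   `p_QM`, `QE`, `df_E`, `tau2_resid`, `tau2_total`, `I2_resid`, `R2`,
#'   and `grand_mean` (the random-effects weighted grand mean reported
#'   alongside, since a single SMD summary is conventional in moderator
#'   tables).
#' @export
fit_meta_regression <- function(records, moderator, outcome, alpha = 0.05,
                                tau2_method = c("MM", "REML")) {
  tau2_method <- match.arg(tau2_method)
  continuous <- identical(moderator, "dose")
  if (!continuous && !moderator %in% .MODERATORS)
    stop("unknown moderator '", moderator, "'", call. = FALSE)
  df <- as.data.frame(records)
  df <- df[df$outcome == outcome, , drop = FALSE]
  if (!nrow(df)) stop("no comparisons for outcome '", outcome, "'",
                      call. = FALSE)
  eff <- compute_effects(df)
  g <- eff$g; v <- eff$var; k <- length(g)

  if (continuous) {
    x <- df$dose_g_per_kg
    if (stats::sd(x) == 0)
      stop("degenerate design: dose has no spread", call. = FALSE)
    X <- cbind(intercept = 1, dose = x - mean(x))
  } else {
    f <- droplevels(factor(eff[[moderator]]))
    if (nlevels(f) < 2)
      stop("degenerate design: moderator '", moderator,
           "' has a single level", call. = FALSE)
    X <- stats::model.matrix(~ f)
    colnames(X) <- c("intercept", paste0(moderator, ":", levels(f)[-1]))
  }
  p <- ncol(X)
  if (k < p + 1)
    stop("too few comparisons (k = ", k, ") for ", p - 1,
         " moderator df", call. = FALSE)

  mm <- .mom_tau2_resid(g, v, X)
  t2_resid <- if (tau2_method == "MM") mm$tau2 else {
    # REML on the full design via profiled fixed-point iteration
    t2 <- mm$tau2
    for (i in 1:500) {
      w <- 1 / (v + t2)
      b <- solve(crossprod(X, w * X), crossprod(X, w * g))
      r <- drop(g - X %*% b)
      H <- solve(crossprod(X, w * X))
      adj <- sum(diag(H %*% crossprod(X, w^2 * X)))
      t2_new <- max(0, sum(w^2 * (r^2 - v)) / sum(w^2) + adj / sum(w^2))
      if (abs(t2_new - t2) < 1e-10) break
      t2 <- t2_new
    }
    t2
  }

  w <- 1 / (v + t2_resid)
  XtWX <- crossprod(X, w * X)
  beta <- drop(solve(XtWX, crossprod(X, w * g)))
  vcov_b <- solve(XtWX)
  se_b <- sqrt(diag(vcov_b))
  zb <- beta / se_b
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se_b,
                      z = zb, p = 2 * stats::pnorm(-abs(zb)),
                      row.names = NULL)

  nonint <- seq_len(p)[-1]
  QM <- drop(crossprod(beta[nonint],
                       solve(vcov_b[nonint, nonint, drop = FALSE],
                             beta[nonint])))
  df_M <- length(nonint)

  t2_total <- dl_tau2(eff)
  R2 <- if (t2_total > 0) max(0, 100 * (1 - t2_resid / t2_total)) else 0
  I2_resid <- if (mm$QE > 0) max(0, 100 * (mm$QE - mm$df_E) / mm$QE) else 0

  structure(list(
    moderator = moderator, outcome = outcome, k = k,
    coefficients = coefs, QM = QM, df_M = df_M,
    p_QM = stats::pchisq(QM, df_M, lower.tail = FALSE),
    QE = mm$QE, df_E = mm$df_E,
    tau2_resid = t2_resid, tau2_total = t2_total,
    I2_resid = I2_resid, R2 = R2,
    grand_mean = random_effects_pool(eff, alpha)$pooled$estimate,
    alpha = alpha), class = "ftlm_metareg")
}

#' @export
print.ftlm_metareg <- function(x, ...) {
  cat(sprintf(
    "meta-regression of %s on %s: k = %d, QM = %.2f (df = %d, %s), R2 = %.0f%%, residual I2 = %.0f%%\n",
    x$outcome, x$moderator, x$k, x$QM, x$df_M, format_p(x$p_QM), x$R2,
    x$I2_resid))
  invisible(x)
}
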