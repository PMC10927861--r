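#' Rosenberg's weighted fail-safe number
#'
#' The number of unpublished null-effect studies, each carrying the mean
#' fixed-effect weight \eqn{\bar w = \sum w_i / k}, that would have to be
#' added to the evidence base to lift the combined two-sided p-value to
#' alpha. With \eqn{S = \sum w_i g_i} and critical value
#' \eqn{z_{1-\alpha/2}},
#' \deqn{N_{fs} = \left\lceil \max\!\left(0,\;
#'   \frac{S^2 / z^2_{1-\alpha/2} - \sum w_i}{\bar w}\right)\right\rceil.}
#' If the observed combined effect is already non-significant at alpha the
#' fail-safe number is 0. This is the fixed-effect weighted variant.
#'
#' @inheritParams fixed_effect_pool
#' @param alpha Target significance level (default 0.05).
#' @param weights `"fixed"` (default) or `"random"`: whether the combined
#'   test and the appended null studies use fixed-effect weights
#'   \eqn{1/var_i} or random-effects weights \eqn{1/(var_i + \hat\tau^2)}.
#' @return Non-negative integer fail-safe number.
#' @export
rosenberg_fsn <- function(effects, alpha = 0.05,
                          weights = c("fixed", "random")) {
  weights <- match.arg(weights)
  e <- .as_gv(effects)
  w <- if (weights == "fixed") 1 / e$v else {
    if (e$k < 2) stop("random-effects weights need k >= 2", call. = FALSE)
    1 / (e$v + dl_tau2(effects))
  }
  S <- sum(w * e$g)
  z <- S / sqrt(sum(w))
  p <- 2 * stats::pnorm(-abs(z))
  if (p >= alpha) return(0L)
  zc <- stats::qnorm(1 - alpha / 2)
  wbar <- sum(w) / e$k
  as.integer(ceiling(max(0, (S^2 / zc^2 - sum(w)) / wbar)))
}

#' Robustness threshold for the fail-safe number
#'
#' A pooled result is considered robust to publication bias when the
#' fail-safe number exceeds five times the number of pooled comparisons
#' plus ten.
#'
#' @param n_comparisons Number of comparisons actually pooled (>= 0).
#' @return `5 * n_comparisons + 10`. Vectorized.
#' @examples
#' robustness_threshold(84) # 430
#' @export
robustness_threshold <- function(n_comparisons) {
  stopifnot(is.numeric(n_comparisons))
  if (any(n_comparisons < 0)) stop("n_comparisons must be >= 0",
                                   call. = FALSE)
  5 * n_comparisons + 10
}

#' Publication-bias robustness assessment
#'
#' Bundles the fail-safe number with the Nfs > 5n + 10 decision rule
#' (strict inequality) and the observed significance of the weighted
#' combined effect.
#'
#' @inheritParams rosenberg_fsn
#' @return An `ftlm_bias` list: `Nfs`, `n_comparisons`, `threshold`,
#'   `robust`, `observed_significance`, `target_significance`.
#' @export
assess_robustness <- function(effects, alpha = 0.05,
                              weights = c("fixed", "random")) {
  weights <- match.arg(weights)
  e <- .as_gv(effects)
  w <- if (weights == "fixed") 1 / e$v else 1 / (e$v + dl_tau2(effects))
  z <- sum(w * e$g) / sqrt(sum(w))
  p <- 2 * stats::pnorm(-abs(z))
  nfs <- rosenberg_fsn(effects, alpha, weights)
  thr <- robustness_threshold(e$k)
  structure(list(
    Nfs = nfs, n_comparisons = e$k, threshold = thr,
    robust = nfs > thr,
    observed_significance = p, target_significance = alpha),
    class = "ftlm_bias")
}

#' @export
print.ftlm_bias <- function(x, ...) {
  cat(sprintf(
    "fail-safe N = %d, n = %d, threshold 5n+10 = %d -> %s (OS %s, TS %.2f)\n",
    x$Nfs, x$n_comparisons, x$threshold,
    if (x$robust) "robust" else "not robust",
    format_p(x$observed_significance), x$target_significance))
  invisible(x)
}
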