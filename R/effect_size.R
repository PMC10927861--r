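#' Hedges' g standardized mean difference for a two-arm comparison
#'
#' Computes the bias-corrected standardized mean difference (the SMD used
#' throughout the pipeline) and its large-sample sampling variance from
#' per-arm summary statistics. With pooled standard deviation
#' \deqn{s_p = \sqrt{\frac{(n_t-1)s_t^2 + (n_c-1)s_c^2}{n_t+n_c-2}},}
#' the raw effect is \eqn{d = (\bar x_t - \bar x_c)/s_p}, the small-sample
#' correction is \eqn{J = 1 - 3/(4m - 1)} with \eqn{m = n_t+n_c-2}, and
#' \deqn{g = J d, \qquad
#'   \widehat{var}(g) = \frac{n_t+n_c}{n_t n_c} + \frac{g^2}{2(n_t+n_c)}.}
#'
#' The sign convention is treated minus control everywhere, so outcomes
#' where lower is better (FCR, drip loss, abdominal fat, crypt depth) show
#' improvement as negative g. No per-outcome sign flipping is applied.
#'
#' @param mean_t,sd_t,n_t Treated-arm mean, SD (>= 0) and replicate count
#'   (>= 2).
#' @param mean_c,sd_c,n_c Control-arm mean, SD (>= 0) and replicate count
#'   (>= 2).
#' @return A one-row data.frame of class `ftlm_effect` with columns `g`,
#'   `var`, `se`. Vectorized: equal-length inputs give one row each.
#' @examples
#' hedges_g(12, 2, 10, 10, 2, 10) # g ~ 0.9577, var ~ 0.2229
#' @export
hedges_g <- function(mean_t, sd_t, n_t, mean_c, sd_c, n_c) {
  stopifnot(is.numeric(mean_t), is.numeric(sd_t), is.numeric(n_t),
            is.numeric(mean_c), is.numeric(sd_c), is.numeric(n_c))
  if (any(n_t < 2 | n_c < 2))
    stop("both arms need n >= 2 to estimate a pooled SD", call. = FALSE)
  if (any(sd_t < 0 | sd_c < 0)) stop("SDs must be >= 0", call. = FALSE)
  m <- n_t + n_c - 2
  sp <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / m)
  degenerate <- sp == 0 & mean_t != mean_c
  if (any(degenerate))
    stop("degenerate comparison: pooled SD is 0 with unequal means",
         call. = FALSE)
  d <- ifelse(sp == 0, 0, (mean_t - mean_c) / sp)
  J <- 1 - 3 / (4 * m - 1)
  g <- J * d
  v <- (n_t + n_c) / (n_t * n_c) + g^2 / (2 * (n_t + n_c))
  out <- data.frame(g = g, var = v, se = sqrt(v))
  class(out) <- c("ftlm_effect", "data.frame")
  out
}

#' Compute effect sizes for every row of a comparison table
#'
#' Applies [hedges_g()] to each comparison and carries the moderator
#' columns along, producing the per-comparison effect table that pooling,
#' subgroup, meta-regression and publication-bias analyses consume.
#'
#' @param records A `ftlm_comparisons` data.frame (see
#'   [read_comparisons()]).
#' @return A data.frame of class `ftlm_effect` with one row per comparison:
#'   `g`, `var`, `se`, plus `study_id`, `outcome` and the five moderator
#'   columns.
#' @export
compute_effects <- function(records) {
  df <- as.data.frame(records)
  es <- hedges_g(df$mean_t, df$sd_t, df$n_t, df$mean_c, df$sd_c, df$n_c)
  out <- cbind(es,
               df[, c("study_id", "outcome", "strain", "leaf_type",
                      "microbes", "dose_bin", "phase_bin")])
  class(out) <- c("ftlm_effect", "data.frame")
  out
}
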