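#' Text forest representation of an effect set
#'
#' One row per comparison (label, g, CI bounds, percent weight under the
#' pooling model's weights) plus a summary row carrying the pooled result.
#' Weights sum to 100.
#'
#' @inheritParams fixed_effect_pool
#' @param pooled An `ftlm_pooled` result for the same effect set (its
#'   model decides the weights: fixed-effect \eqn{1/var_i} or
#'   random-effects \eqn{1/(var_i + \hat\tau^2)}).
#' @return Data.frame with columns `label`, `g`, `ci_low`, `ci_high`,
#'   `weight_pct`; final row is the summary.
#' @export
render_forest_table <- function(effects, pooled) {
  e <- .as_gv(effects)
  zc <- stats::qnorm(1 - pooled$alpha / 2)
  w <- if (identical(pooled$model, "random") && e$k >= 2)
    1 / (e$v + dl_tau2(effects)) else 1 / e$v
  labels <- if (is.data.frame(effects) && !is.null(effects$study_id))
    make.unique(as.character(effects$study_id)) else
    sprintf("comparison-%d", seq_len(e$k))
  out <- data.frame(
    label = c(labels, sprintf("%s-effects summary", pooled$model)),
    g = c(e$g, pooled$estimate),
    ci_low = c(e$g - zc * sqrt(e$v), pooled$ci_low),
    ci_high = c(e$g + zc * sqrt(e$v), pooled$ci_high),
    weight_pct = c(100 * w / sum(w), 100),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# pool one outcome; returns NULL with a warning when k = 1 rules out a
# random-effects pool (degeneracies must not halt the pipeline)
.pool_outcome <- function(eff, outcome, alpha, model) {
  if (nrow(eff) < 2 && model == "random") {
    warning("outcome '", outcome, "' has k = 1; no random-effects pool",
            call. = FALSE)
    return(NULL)
  }
  if (model == "random") random_effects_pool(eff, alpha)
  else list(pooled = fixed_effect_pool(eff, alpha), heterogeneity = NULL)
}

#' Run the full meta-analytic pipeline
#'
#' Executes ingest, effect-size computation, random-effects pooling,
#' subgroup analysis, meta-regression and publication-bias assessment for
#' each requested outcome, and optionally writes every table plus a
#' machine-readable JSON summary to an output directory.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{csv}{path to an extraction CSV, or}
#'     \item{simulate}{a `ftlm_sim_config` (one of the two is required);}
#'     \item{outcomes}{outcome codes to analyse (default: all present);}
#'     \item{moderators}{moderators for subgroup/meta-regression analyses
#'       (default: all five);}
#'     \item{alpha}{significance level (default 0.05);}
#'     \item{model}{`"random"` (default) or `"fixed"`;}
#'     \item{out}{optional output directory.}
#'   }
#' @return An `ftlm_report` list: `records`, and per outcome a list with
#'   `effects`, `pooled`, `heterogeneity`, `forest`, `subgroups` (one
#'   `ftlm_subgroup` per moderator), `metareg` (one `ftlm_metareg` per
#'   moderator), `bias`; plus `meta` (alpha, model, seed, package
#'   version).
#' @export
run_pipeline <- function(config) {
  # [[ ]] access throughout: $ would partially match 'out' to 'outcomes'
  alpha <- config[["alpha"]] %||% 0.05
  model <- match.arg(config[["model"]] %||% "random", c("random", "fixed"))
  moderators <- config[["moderators"]] %||% .MODERATORS
  records <- if (!is.null(config[["csv"]])) read_comparisons(config[["csv"]])
    else if (!is.null(config[["simulate"]]))
      simulate_ensemble(config[["simulate"]])$records
    else stop("config needs either 'csv' or 'simulate'", call. = FALSE)
  outcomes <- config[["outcomes"]] %||% unique(records$outcome)

  per_outcome <- lapply(outcomes, function(oc) {
    sub <- records[records$outcome == oc, , drop = FALSE]
    if (!nrow(sub)) {
      warning("no comparisons for outcome '", oc, "'", call. = FALSE)
      return(NULL)
    }
    eff <- compute_effects(sub)
    pool <- .pool_outcome(eff, oc, alpha, model)
    if (is.null(pool)) return(NULL)
    subgroups <- lapply(moderators, function(m)
      tryCatch(subgroup_analysis(sub, m, oc, alpha),
               error = function(e) {
                 warning("subgroup ", m, "/", oc, ": ", conditionMessage(e),
                         call. = FALSE); NULL
               }))
    names(subgroups) <- moderators
    metareg <- lapply(moderators, function(m)
      tryCatch(fit_meta_regression(sub, m, oc, alpha),
               error = function(e) {
                 warning("meta-regression ", m, "/", oc, ": ",
                         conditionMessage(e), call. = FALSE); NULL
               }))
    names(metareg) <- moderators
    list(outcome = oc, effects = eff, pooled = pool$pooled,
         heterogeneity = pool$heterogeneity,
         forest = render_forest_table(eff, pool$pooled),
         subgroups = Filter(Negate(is.null), subgroups),
         metareg = Filter(Negate(is.null), metareg),
         bias = assess_robustness(eff, alpha))
  })
  names(per_outcome) <- outcomes
  bundle <- structure(list(
    records = records,
    outcomes = Filter(Negate(is.null), per_outcome),
    meta = list(alpha = alpha, model = model,
                seed = config[["simulate"]][["seed"]],
                version = as.character(utils::packageVersion("ftlmeta")))),
    class = "ftlm_report")
  if (!is.null(config[["out"]])) export_report(bundle, config[["out"]])
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten one outcome's results into summary-ready plain lists
.summarize_outcome <- function(oc) {
  list(
    k = oc$pooled$k,
    pooled = list(estimate = oc$pooled$estimate, ci_low = oc$pooled$ci_low,
                  ci_high = oc$pooled$ci_high, z = oc$pooled$z,
                  p = oc$pooled$p, model = oc$pooled$model),
    heterogeneity = if (!is.null(oc$heterogeneity))
      oc$heterogeneity[c("Q", "df", "p_Q", "I2", "tau2")],
    bias = oc$bias[c("Nfs", "n_comparisons", "threshold", "robust",
                     "observed_significance", "target_significance")],
    metareg = lapply(oc$metareg, function(m)
      m[c("moderator", "k", "QM", "df_M", "p_QM", "tau2_resid",
          "tau2_total", "I2_resid", "R2", "grand_mean")]))
}

#' Export a report bundle as CSV tables plus a JSON summary
#'
#' Writes, per outcome: the normalized records, the forest table, each
#' subgroup table (columns mirroring the moderator tables: level, dataset
#' count, SMD, CI, p, I-squared, p of Q), each meta-regression row
#' (outcome, moderator, k, SMD, QM, p, residual I-squared, R-squared), the
#' publication-bias row (SMD, OS, TS, Nfs, n, 5n+10), and `summary.json`.
#'
#' @param bundle An `ftlm_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_report <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_comparisons(bundle$records, file.path(dir, "records.csv"))
  for (oc in bundle$outcomes) {
    tag <- gsub("[^A-Za-z0-9]+", "_", oc$outcome)
    utils::write.csv(oc$forest,
                     file.path(dir, paste0("forest_", tag, ".csv")),
                     row.names = FALSE)
    for (m in names(oc$subgroups))
      utils::write.csv(as.data.frame(oc$subgroups[[m]]),
                       file.path(dir, sprintf("subgroup_%s_%s.csv", tag, m)),
                       row.names = FALSE)
    if (length(oc$metareg)) {
      mr <- do.call(rbind, lapply(oc$metareg, function(x)
        data.frame(outcome = oc$outcome, moderator = x$moderator, k = x$k,
                   SMD = x$grand_mean, QM = x$QM, p = x$p_QM,
                   I2_resid = x$I2_resid, R2 = x$R2)))
      utils::write.csv(mr, file.path(dir, paste0("metareg_", tag, ".csv")),
                       row.names = FALSE)
    }
    b <- oc$bias
    utils::write.csv(
      data.frame(outcome = oc$outcome, k = b$n_comparisons,
                 SMD = oc$pooled$estimate, OS = b$observed_significance,
                 TS = b$target_significance, Nfs = b$Nfs,
                 n = b$n_comparisons, threshold = b$threshold,
                 robust = b$robust),
      file.path(dir, paste0("bias_", tag, ".csv")), row.names = FALSE)
  }
  summary <- list(meta = bundle$meta,
                  outcomes = lapply(bundle$outcomes, .summarize_outcome))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' @export
print.ftlm_report <- function(x, ...) {
  cat("meta-analysis report:", length(x$outcomes), "outcome(s),",
      nrow(x$records), "comparisons\n")
  for (oc in x$outcomes) {
    cat("\n[", oc$outcome, "] ", sep = "")
    print(oc$pooled)
    if (!is.null(oc$heterogeneity)) print(oc$heterogeneity)
  }
  invisible(x)
}
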