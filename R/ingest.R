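#' Convert a standard error of the mean to a standard deviation
#'
#' Applies the conversion SD = SE * sqrt(n), where n is the number of
#' replicates in the arm. Used during normalization of extraction rows
#' that report SE instead of SD.
#'
#' @param se Standard error of the arm mean (non-negative).
#' @param n Replicate count of the arm (integer, at least 1).
#' @return The standard deviation, `se * sqrt(n)`. Vectorized.
#' @examples
#' se_to_sd(2, 25)   # 10
#' se_to_sd(1.5, 16) # 6
#' @export
se_to_sd <- function(se, n) {
  stopifnot(is.numeric(se), is.numeric(n))
  if (any(se < 0, na.rm = TRUE)) stop("se must be >= 0", call. = FALSE)
  if (any(n < 1, na.rm = TRUE)) stop("n must be >= 1", call. = FALSE)
  se * sqrt(n)
}

#' Convert a standard deviation to a standard error of the mean
#'
#' Inverse of [se_to_sd()].
#'
#' @inheritParams se_to_sd
#' @param sd Standard deviation of the arm (non-negative).
#' @return `sd / sqrt(n)`. Vectorized.
#' @export
sd_to_se <- function(sd, n) {
  stopifnot(is.numeric(sd), is.numeric(n))
  if (any(sd < 0, na.rm = TRUE)) stop("sd must be >= 0", call. = FALSE)
  if (any(n < 1, na.rm = TRUE)) stop("n must be >= 1", call. = FALSE)
  sd / sqrt(n)
}

#' Assign a supplementation dose to its subgroup bin
#'
#' Doses (g/kg feed) are partitioned into the three subgroup bands used in
#' moderator analyses: LOW (0-5], MID (5-10], HIGH (10-14]. The partition is
#' half-open so every real dose in \[0, 14\] maps to exactly one bin; a dose
#' of 5.5 g/kg falls in MID.
#'
#' @param dose Numeric dose in g/kg feed, in \[0, 14\]. Vectorized.
#' @return Factor with levels `LOW`, `MID`, `HIGH`.
#' @examples
#' assign_dose_bin(c(5, 7, 14)) # LOW MID HIGH
#' @export
assign_dose_bin <- function(dose) {
  stopifnot(is.numeric(dose))
  if (any(dose < 0 | dose > 14, na.rm = TRUE))
    stop("dose must be in [0, 14] g/kg feed", call. = FALSE)
  cut(dose, breaks = c(-Inf, 5, 10, Inf), labels = .DOSE_BIN_LEVELS,
      right = TRUE)
}

#' Assign a rearing-phase day window to its subgroup bin
#'
#' Windows ending by day 21 are `starter`; windows that begin at day 0 or 1,
#' extend past day 21 and span more than 21 days cover both starter and
#' finisher territory and are `overall`; everything else is `finisher`.
#' This rule classifies every phase window reported by the source trials
#' (1-21 starter, 22-42 finisher, 0-42 and 1-56 overall, 15-35 finisher).
#'
#' @param phase_start First day of the window (0-56).
#' @param phase_end Last day of the window (0-56, greater than
#'   `phase_start`). Vectorized with `phase_start`.
#' @return Factor with levels `starter`, `finisher`, `overall`.
#' @export
assign_phase_bin <- function(phase_start, phase_end) {
  stopifnot(is.numeric(phase_start), is.numeric(phase_end))
  bad <- phase_start < 0 | phase_end > 56 | phase_start >= phase_end
  if (any(bad, na.rm = TRUE))
    stop("phase windows must satisfy 0 <= start < end <= 56", call. = FALSE)
  out <- ifelse(phase_end <= 21, "starter",
         ifelse(phase_start <= 1 & phase_end > 21 &
                (phase_end - phase_start) > 21, "overall", "finisher"))
  factor(out, levels = .PHASE_BIN_LEVELS)
}

# trim, collapse internal whitespace, casefold
.canon_token <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

# match x against a closed vocabulary, returning canonical spellings;
# mixtures ("a + b") are matched on the sorted set of component organisms
.match_vocab <- function(x, vocab, field, split_mixture = FALSE) {
  key <- .canon_token(x)
  vkey <- .canon_token(vocab)
  if (split_mixture) {
    sort_mix <- function(k) {
      parts <- sort(trimws(strsplit(k, "\\+")[[1]]))
      paste(parts, collapse = " + ")
    }
    key <- vapply(key, sort_mix, character(1))
    vkey <- vapply(vkey, sort_mix, character(1))
  }
  idx <- match(key, vkey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop(sprintf("unknown %s value '%s' in row %d", field, x[bad[1]], bad[1]),
         call. = FALSE)
  }
  vocab[idx]
}

# normalize one arm: fill sd from se when sd is missing (never overwrite a
# provided sd); error when both are absent
.normalize_arm <- function(mean, sd, se, n, arm, rows) {
  both_missing <- is.na(sd) & is.na(se)
  if (any(both_missing))
    stop(sprintf("row %d: both sd_%s and se_%s are missing",
                 rows[which(both_missing)[1]], arm, arm), call. = FALSE)
  fill <- is.na(sd)
  sd[fill] <- se_to_sd(se[fill], n[fill])
  sd
}

#' Read a per-comparison extraction table
#'
#' Reads the comma-separated extraction dialect (one row per
#' study x dose x outcome x phase comparison), validates it against the
#' closed moderator and outcome vocabularies, normalizes categorical
#' spellings, converts per-arm SE to SD where SD is absent, and attaches the
#' derived `dose_bin` and `phase_bin` moderator columns.
#'
#' Expected columns: `study_id, country, strain, leaf_type, microbes,
#' dose_g_per_kg, phase_start_day, phase_end_day, outcome, mean_c, sd_c,
#' se_c, n_c, mean_t, sd_t, se_t, n_t`. Empty strings are missing values;
#' per row, at most one of `sd_*`/`se_*` may be empty per arm.
#'
#' @param csv_source Path to a CSV file, a connection, or a data.frame
#'   already holding the dialect columns.
#' @return A `ftlm_comparisons` data.frame: the input rows (order preserved)
#'   with normalized categoricals, `sd_c`/`sd_t` always populated, and
#'   factor columns `dose_bin`, `phase_bin`.
#' @seealso [write_comparisons()], [validate_records()]
#' @export
read_comparisons <- function(csv_source) {
  df <- if (is.data.frame(csv_source)) csv_source
        else utils::read.csv(csv_source, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"), fileEncoding = "UTF-8")
  missing_cols <- setdiff(.CSV_COLUMNS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[, .CSV_COLUMNS]
  for (col in c("dose_g_per_kg", "phase_start_day", "phase_end_day",
                "mean_c", "sd_c", "se_c", "mean_t", "sd_t", "se_t"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("n_c", "n_t")) df[[col]] <- as.integer(df[[col]])

  if (any(is.na(df$study_id)))
    warning("missing study_id in ", sum(is.na(df$study_id)), " row(s)")
  if (any(is.na(df$country)))
    warning("missing country metadata (tolerated; not used in computation)")

  df$strain <- .match_vocab(df$strain, .STRAINS, "strain")
  df$leaf_type <- .match_vocab(df$leaf_type, .LEAF_TYPES, "leaf_type")
  df$microbes <- .match_vocab(df$microbes, .MICROBES, "microbes",
                              split_mixture = TRUE)
  df$outcome <- .match_vocab(df$outcome, .OUTCOMES, "outcome")

  rows <- seq_len(nrow(df))
  df$sd_c <- .normalize_arm(df$mean_c, df$sd_c, df$se_c, df$n_c, "c", rows)
  df$sd_t <- .normalize_arm(df$mean_t, df$sd_t, df$se_t, df$n_t, "t", rows)
  df$dose_bin <- assign_dose_bin(df$dose_g_per_kg)
  df$phase_bin <- assign_phase_bin(df$phase_start_day, df$phase_end_day)

  viol <- validate_records(df)
  if (length(viol))
    stop("invalid extraction table:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  .warn_shared_controls(df)
  class(df) <- c("ftlm_comparisons", "data.frame")
  df
}

# multi-dose trials contribute several comparisons sharing one control arm;
# they are pooled as independent (matching the source analyses) but flagged
.warn_shared_controls <- function(df) {
  key <- paste(df$study_id, df$outcome, df$phase_start_day, df$phase_end_day,
               df$mean_c, df$sd_c, df$n_c, sep = "\r")
  dup <- duplicated(key) & !is.na(df$study_id)
  if (any(dup))
    warning(sum(dup), " comparison(s) appear to share a control arm with ",
            "another row (multi-dose trial); they are pooled as independent",
            call. = FALSE)
  invisible(df)
}

#' Write a normalized comparison table
#'
#' Writes the same CSV dialect that [read_comparisons()] accepts, so a table
#' round-trips through write + read unchanged (up to categorical
#' normalization, which read applies).
#'
#' @param records A `ftlm_comparisons` data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_comparisons <- function(records, path) {
  df <- as.data.frame(records)[, .CSV_COLUMNS]
  # full precision so a re-read reproduces every double bit-for-bit
  for (col in names(df))
    if (is.double(df[[col]]))
      df[[col]] <- ifelse(is.na(df[[col]]), NA_character_,
                          sprintf("%.17g", df[[col]]))
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate comparison records against the type invariants
#'
#' Checks every row of a comparison table against the domain invariants
#' (dose range, phase window, arm replicate counts, non-negative SDs,
#' outcome vocabulary). Violations are returned as data, not raised.
#'
#' @param records A data.frame of comparison rows (normalized or raw, as
#'   long as the dialect columns are present).
#' @return Character vector of violation descriptions, each naming the row
#'   index, field and rule; empty when all rows are valid.
#' @export
validate_records <- function(records) {
  df <- as.data.frame(records)
  v <- character(0)
  chk <- function(bad, field, rule) {
    bad <- which(bad | is.na(bad))
    if (length(bad))
      sprintf("row %d: field '%s' violates '%s'", bad, field, rule)
    else character(0)
  }
  v <- c(v,
    chk(df$dose_g_per_kg < 0 | df$dose_g_per_kg > 14, "dose_g_per_kg",
        "dose in [0, 14] g/kg"),
    chk(df$phase_start_day < 0 | df$phase_start_day >= df$phase_end_day,
        "phase_start_day", "0 <= start < end"),
    chk(df$phase_end_day > 56, "phase_end_day", "end <= 56"),
    chk(df$n_c < 1, "n_c", "n >= 1"),
    chk(df$n_t < 1, "n_t", "n >= 1"),
    chk(!is.na(df$sd_c) & df$sd_c < 0, "sd_c", "sd >= 0"),
    chk(!is.na(df$sd_t) & df$sd_t < 0, "sd_t", "sd >= 0"),
    chk(!(.canon_token(df$outcome) %in% .canon_token(.OUTCOMES)), "outcome",
        "outcome in closed vocabulary"))
  v
}
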