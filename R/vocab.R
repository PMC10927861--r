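#' Closed vocabularies for the extraction table
#'
#' The extraction table records five study-level moderators with closed
#' vocabularies: broiler strain, leaf-meal species, fermentation microbes
#' (single organisms or named mixtures), supplementation dose (continuous,
#' g/kg feed, later binned) and rearing phase (day window, later binned).
#' Matching is case- and whitespace-insensitive; mixtures are matched on the
#' sorted set of component organisms regardless of listing order.
#'
#' @name ftlm-vocab
#' @keywords internal
NULL

.STRAINS <- c("Arbor Acres", "Yellow feathered", "Lohmann")

.LEAF_TYPES <- c("G. biloba", "M. alba", "S. androgynus", "C. album")

# single organisms appearing in fermentation protocols
.MICROBE_ORGANISMS <- c(
  "A. niger", "B. subtilis", "B. licheniform", "C. utilis",
  "T. harzianum", "L. plantarum", "Lactobacillus spp", "N. crassa",
  "S. cerevisiae", "Saccharomycetes", "Lactobacillus"
)

# named mixtures; components sorted alphabetically, joined with " + "
.MICROBE_MIXTURES <- c(
  "A. niger + C. utilis",
  "A. niger + C. utilis + N. crassa",
  "B. subtilis + Lactobacillus + Saccharomycetes",
  "B. subtilis + L. plantarum + S. cerevisiae"
)

.MICROBES <- c(.MICROBE_ORGANISMS, .MICROBE_MIXTURES)

.INTESTINAL_SEGMENTS <- c("duodenum", "jejunum", "ileum")
.MUSCLES <- c("breast_muscle", "thigh_muscle")

.OUTCOMES <- c(
  "FI", "ADG", "FCR",
  "cholesterol", "triglycerides", "HDL", "LDL",
  paste0("VH_", .INTESTINAL_SEGMENTS),
  paste0("CD_", .INTESTINAL_SEGMENTS),
  paste0("VHCD_", .INTESTINAL_SEGMENTS),
  "dressing_percentage", "breast", "thigh", "abdominal_fat",
  paste0("pH_", .MUSCLES),
  paste0("drip_loss_", .MUSCLES),
  paste0("shear_force_", .MUSCLES),
  paste0("L_", .MUSCLES), paste0("a_", .MUSCLES), paste0("b_", .MUSCLES)
)

.DOSE_BIN_LEVELS <- c("LOW", "MID", "HIGH")
.PHASE_BIN_LEVELS <- c("starter", "finisher", "overall")

.MODERATORS <- c("strain", "leaf_type", "microbes", "dose_bin", "phase_bin")

# canonical column order of the extraction CSV dialect
.CSV_COLUMNS <- c(
  "study_id", "country", "strain", "leaf_type", "microbes",
  "dose_g_per_kg", "phase_start_day", "phase_end_day", "outcome",
  "mean_c", "sd_c", "se_c", "n_c", "mean_t", "sd_t", "se_t", "n_t"
)

#' Moderator names accepted by subgroup and meta-regression analyses
#' @return Character vector of valid moderator column names.
#' @export
ftlm_moderators <- function() .MODERATORS

#' Outcome vocabulary of the extraction table
#' @return Character vector of valid outcome codes.
#' @export
ftlm_outcomes <- function() .OUTCOMES
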