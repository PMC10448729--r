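#' MM-PC fraction of nucleated events
#'
#' Disease burden is the number of malignant plasma-cell events divided by
#' the analytical input (total acquired nucleated events across both
#' tubes): 10 events in 10^7 is a fraction of 1e-6.
#'
#' @param mm_events Malignant plasma-cell event count(s).
#' @param analytical_input Total acquired nucleated events; must be > 0.
#' @return Fraction(s).
#' @export
mm_pc_fraction <- function(mm_events, analytical_input) {
  check_non_negative(mm_events, "mm_events")
  check_positive(analytical_input, "analytical_input")
  mm_events / analytical_input
}

#' Disease-burden band from a count rescaled to 10^7 events
#'
#' Bands are defined on MM-PC events per 10^7 nucleated cells:
#' `ultra_low` 5-9, `low` 10-19, `intermediate` 20-100, `high` above 100;
#' below 5 rescaled events no band is assigned (`none`). For analytical
#' inputs other than 10^7 the count is rescaled as
#' `round(mm_events * 1e7 / analytical_input)`.
#'
#' @inheritParams mm_pc_fraction
#' @return Factor with levels `none`, `ultra_low`, `low`, `intermediate`,
#'   `high`.
#' @export
burden_band <- function(mm_events, analytical_input) {
  check_non_negative(mm_events, "mm_events")
  check_positive(analytical_input, "analytical_input")
  scaled <- round(mm_events * 1e7 / analytical_input)
  out <- dplyr::case_when(
    scaled > 100 ~ "high",
    scaled >= 20 ~ "intermediate",
    scaled >= 10 ~ "low",
    scaled >= 5 ~ "ultra_low",
    .default = "none"
  )
  factor(out, levels = c("none", "ultra_low", "low", "intermediate", "high"))
}

#' Call MRD status at a virtual sensitivity threshold
#'
#' A specimen is `positive` when its MM-PC fraction reaches the threshold:
#' detected disease remains detected however coarse the effective
#' sensitivity, so adequacy problems never suppress a positive call. A
#' specimen below the threshold is `negative` only when the effective
#' sensitivity (the coarser of the nominal assay limit and any revised
#' limit of detection from low input) actually reaches the threshold;
#' otherwise disease cannot be ruled out at that level and the call is
#' `not_evaluable`.
#'
#' @param mm_events,analytical_input As in [mm_pc_fraction()] (vectors
#'   recycle).
#' @param threshold Virtual sensitivity threshold (fraction), e.g. `1e-6`.
#' @param effective_sensitivity Achieved detection limit for the specimen;
#'   defaults to the threshold itself (fully adequate specimen).
#' @return Tibble with `threshold`, `mm_pc_fraction`, `status`,
#'   `burden_band` and `effective_sensitivity`.
#' @examples
#' call_mrd(15, 1e7, threshold = 1e-5) # negative, band "low"
#' call_mrd(15, 1e7, threshold = 1e-6) # positive at the finer threshold
#' @export
call_mrd <- function(mm_events, analytical_input, threshold,
                     effective_sensitivity = threshold) {
  check_positive(threshold, "threshold")
  if (any(analytical_input <= 0)) {
    stop("`analytical_input` must be positive.", call. = FALSE)
  }
  frac <- mm_pc_fraction(mm_events, analytical_input)
  status <- dplyr::case_when(
    frac >= threshold ~ "positive",
    effective_sensitivity > threshold ~ "not_evaluable",
    .default = "negative"
  )
  tibble::tibble(
    threshold = threshold,
    mm_pc_fraction = frac,
    status = factor(status, levels = c("positive", "negative", "not_evaluable")),
    burden_band = burden_band(mm_events, analytical_input),
    effective_sensitivity = pmax(effective_sensitivity, 0)
  )
}

#' Call MRD for a cohort at one or more virtual sensitivities
#'
#' Joins the specimen table with its QC assessment, derives each specimen's
#' effective sensitivity as the coarser of the nominal assay limit and the
#' revised limit of detection (when the analytical input fell short), and
#' calls MRD at every requested threshold.
#'
#' @param records Specimen tibble.
#' @param qc QC tibble from [assess_specimens()] (or [assess_input()]).
#' @param thresholds Virtual sensitivities to call at, coarse or fine in
#'   any order; default the four standard reporting levels.
#' @param nominal_lod The assay's nominal limit of detection (default
#'   1e-6).
#' @return Tibble with one row per specimen x threshold.
#' @export
call_mrd_cohort <- function(records, qc,
                            thresholds = c(1e-4, 1e-5, 2e-6, 1e-6),
                            nominal_lod = 1e-6) {
  check_positive(thresholds, "thresholds")
  joined <- dplyr::inner_join(
    dplyr::select(records, "specimen_id", "mm_pc_events"),
    dplyr::select(qc, "specimen_id", "analytical_input", "revised_lod"),
    by = "specimen_id"
  )
  if (nrow(joined) != nrow(records)) {
    stop("`records` and `qc` do not describe the same specimens.", call. = FALSE)
  }
  eff <- pmax(nominal_lod, dplyr::coalesce(joined$revised_lod, 0))
  purrr::map(thresholds, function(t) {
    dplyr::bind_cols(
      tibble::tibble(specimen_id = joined$specimen_id),
      call_mrd(joined$mm_pc_events, joined$analytical_input, t, eff)
    )
  }) |>
    purrr::list_rbind()
}

#' Classify a serial MRD transition between two assessments
#'
#' Serial assessments moving between the low (10-19 MM-PCs per 10^7) and
#' high (>100) bands within a follow-up window are the strongest in-vivo
#' evidence that counts near the detection limit are real. Transitions
#' that end (or start) in the ultra-low or low band and lack phenotypic
#' and clonal concordance between the two measurements are flagged as
#' suspected false positives.
#'
#' @param band_t1,band_t2 Burden bands of the earlier and later calls
#'   (levels of [burden_band()]).
#' @param phenotype_concordant Logical: did the MM-PC population show the
#'   same phenotype/clonality at both assessments?
#' @return Tibble with `transition` in `low_to_high`, `high_to_low`,
#'   `high_to_ultra_low`, `stable`, `other`, and
#'   `suspected_false_positive`.
#' @export
classify_transition <- function(band_t1, band_t2, phenotype_concordant) {
  band_t1 <- as.character(band_t1)
  band_t2 <- as.character(band_t2)
  transition <- dplyr::case_when(
    band_t1 == band_t2 ~ "stable",
    band_t1 == "low" & band_t2 == "high" ~ "low_to_high",
    band_t1 == "high" & band_t2 == "low" ~ "high_to_low",
    band_t1 == "high" & band_t2 == "ultra_low" ~ "high_to_ultra_low",
    .default = "other"
  )
  near_limit <- band_t1 %in% c("ultra_low", "low") | band_t2 %in% c("ultra_low", "low")
  tibble::tibble(
    transition = factor(
      transition,
      levels = c("low_to_high", "high_to_low", "high_to_ultra_low", "stable", "other")
    ),
    suspected_false_positive = near_limit & !phenotype_concordant
  )
}
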