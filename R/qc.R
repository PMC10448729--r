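#' Assay-input adequacy policy
#'
#' The recommended staining input for MRD testing by next-generation flow is
#' 20 x 10^6 cells (10 x 10^6 per tube); specimens staining at least
#' 15 x 10^6 are treated as marginal because they still usually yield the
#' required analytical input of 10 x 10^6 acquired nucleated events
#' (at least 5 x 10^6 per tube).
#'
#' @param full_stained_cells Stained-cell count for a fully adequate input.
#' @param marginal_stained_cells Lower bound of the marginal band; must be
#'   below `full_stained_cells`.
#' @param required_acquired_events Total acquired events needed to call MRD
#'   at nominal sensitivity.
#' @param per_tube_minimum Minimum events per tube.
#' @return A list of class `mrd_input_policy`.
#' @export
input_policy <- function(full_stained_cells = 20e6,
                         marginal_stained_cells = 15e6,
                         required_acquired_events = 10e6,
                         per_tube_minimum = 5e6) {
  if (!(marginal_stained_cells < full_stained_cells)) {
    stop("`marginal_stained_cells` must be below `full_stained_cells`.", call. = FALSE)
  }
  if (per_tube_minimum * 2 > required_acquired_events) {
    stop("`per_tube_minimum` x 2 must not exceed `required_acquired_events`.", call. = FALSE)
  }
  structure(
    list(
      full_stained_cells = full_stained_cells,
      marginal_stained_cells = marginal_stained_cells,
      required_acquired_events = required_acquired_events,
      per_tube_minimum = per_tube_minimum
    ),
    class = "mrd_input_policy"
  )
}

#' Hemodilution adequacy policy
#'
#' Mast cells are marrow-resident and essentially absent from peripheral
#' blood, so a depleted mast-cell fraction flags a hemodiluted aspirate.
#' Defaults are cohort-level cut-offs: adequate at or above 0.0048%
#' (the average lower limit of normal across time points), marginal at or
#' above 0.002%, suboptimal below. Substitute per-time-point lower limits
#' of normal from [compute_lln()] where a time-point-specific call is
#' wanted.
#'
#' @param adequate_threshold Mast-cell fraction (dimensionless) at or above
#'   which a specimen is adequate.
#' @param marginal_threshold Lower bound of the marginal band; must be below
#'   `adequate_threshold`.
#' @return A list of class `mrd_hemodilution_policy`.
#' @export
hemodilution_policy <- function(adequate_threshold = 4.8e-5,
                                marginal_threshold = 2e-5) {
  if (!(marginal_threshold < adequate_threshold)) {
    stop("`marginal_threshold` must be below `adequate_threshold`.", call. = FALSE)
  }
  structure(
    list(
      adequate_threshold = adequate_threshold,
      marginal_threshold = marginal_threshold
    ),
    class = "mrd_hemodilution_policy"
  )
}

#' Revised limit of detection for a low-input specimen
#'
#' When fewer than the required nucleated events are acquired, calling MRD
#' negative at nominal sensitivity would overstate the assay: the detection
#' limit attainable with `analytical_input` events is the fraction
#' corresponding to 10 malignant plasma cells, `10 / analytical_input`.
#'
#' @param analytical_input Total acquired nucleated events (both tubes).
#' @return Fraction(s); strictly decreasing in the input.
#' @examples
#' compute_revised_lod(10e6) # 1e-06, the nominal sensitivity
#' compute_revised_lod(8539710) # ~1.171e-06
#' @export
compute_revised_lod <- function(analytical_input) {
  check_positive(analytical_input, "analytical_input")
  10 / analytical_input
}

#' Classify specimen hemodilution from mast-cell content
#'
#' @param mast_fraction Observed mast-cell fraction(s) of nucleated events.
#' @param policy A [hemodilution_policy()].
#' @return Factor with levels `adequate`, `marginal`, `suboptimal`.
#' @examples
#' classify_hemodilution(c(8.3e-5, 3e-5, 1.9e-5))
#' @export
classify_hemodilution <- function(mast_fraction, policy = hemodilution_policy()) {
  check_non_negative(mast_fraction, "mast_fraction")
  out <- dplyr::case_when(
    mast_fraction >= policy$adequate_threshold ~ "adequate",
    mast_fraction >= policy$marginal_threshold ~ "marginal",
    .default = "suboptimal"
  )
  factor(out, levels = c("adequate", "marginal", "suboptimal"))
}

#' Lower limit of normal for mast-cell content, per group
#'
#' The lower limit of normal (LLN) is the group mean mast-cell fraction
#' minus one sample standard deviation, floored at zero (early time points
#' can have SD exceeding the mean, and a negative fraction is meaningless).
#' The grouping is exposed because published cut-offs depend on it; the
#' conventional grouping is the clinical time point.
#'
#' @param data Data frame of specimens.
#' @param mast Column of mast-cell fractions (tidy-eval).
#' @param by Grouping column (tidy-eval), typically `timepoint`.
#' @return Tibble with one row per group: `n`, `mast_mean`, `mast_sd`,
#'   `lln`.
#' @examples
#' bm <- generate_cohort(cohort_config(n_specimens = 100, seed = 2))
#' bm |>
#'   dplyr::mutate(mast_fraction = mast_cell_events /
#'     (acquired_events_tube_a + acquired_events_tube_b)) |>
#'   compute_lln(mast_fraction, timepoint)
#' @export
compute_lln <- function(data, mast, by) {
  mast <- rlang::enquo(mast)
  by <- rlang::enquo(by)
  out <- data |>
    dplyr::group_by(!!by) |>
    dplyr::summarise(
      n = dplyr::n(),
      mast_mean = mean(!!mast),
      mast_sd = stats::sd(!!mast),
      .groups = "drop"
    )
  small <- out$n < 2
  if (any(small)) {
    stop(sprintf(
      "Need >= 2 mast-cell values per group to compute an LLN; offending group(s): %s.",
      paste(dplyr::pull(out, !!by)[small], collapse = ", ")
    ), call. = FALSE)
  }
  dplyr::mutate(out, lln = pmax(0, .data$mast_mean - .data$mast_sd))
}

#' Aspirate volume needed to reach a target cell input
#'
#' @param cellularity_per_ml Nucleated cells per mL of aspirate.
#' @param target_cells Desired cell input (default the recommended
#'   20 x 10^6).
#' @return Volume in mL.
#' @examples
#' volume_required(11.5e6) # 1.74 mL at average cellularity
#' @export
volume_required <- function(cellularity_per_ml, target_cells = 20e6) {
  check_positive(cellularity_per_ml, "cellularity_per_ml")
  check_non_negative(target_cells, "target_cells")
  target_cells / cellularity_per_ml
}

#' Assess assay-input adequacy for each specimen
#'
#' Categorises the staining input (adequate / marginal / insufficient
#' against the policy's stained-cell thresholds), sums the two tubes into
#' the analytical input, checks the per-tube and total event requirements,
#' and computes the revised limit of detection for specimens short of the
#' required analytical input.
#'
#' @param records Specimen tibble (schema of [generate_cohort()]).
#' @param policy An [input_policy()].
#' @return Tibble with `specimen_id`, `input_category`, `analytical_input`,
#'   `analytical_input_ok` and `revised_lod` (`NA` when the input meets the
#'   requirement).
#' @export
assess_input <- function(records, policy = input_policy()) {
  counts <- c(
    records$stained_cells, records$acquired_events_tube_a,
    records$acquired_events_tube_b
  )
  if (any(counts < 0)) stop("Event and cell counts must be non-negative.", call. = FALSE)
  records |>
    dplyr::transmute(
      specimen_id = .data$specimen_id,
      input_category = factor(
        dplyr::case_when(
          .data$stained_cells >= policy$full_stained_cells ~ "adequate",
          .data$stained_cells >= policy$marginal_stained_cells ~ "marginal",
          .default = "insufficient"
        ),
        levels = c("adequate", "marginal", "insufficient")
      ),
      analytical_input = .data$acquired_events_tube_a + .data$acquired_events_tube_b,
      analytical_input_ok = .data$analytical_input >= policy$required_acquired_events &
        .data$acquired_events_tube_a >= policy$per_tube_minimum &
        .data$acquired_events_tube_b >= policy$per_tube_minimum,
      revised_lod = dplyr::if_else(
        .data$analytical_input < policy$required_acquired_events,
        compute_revised_lod(pmax(.data$analytical_input, 1)),
        NA_real_
      )
    )
}

#' Full specimen quality-control assessment
#'
#' Combines [assess_input()] with hemodilution classification of the
#' observed mast-cell fraction and a low-viability flag.
#'
#' @param records Specimen tibble.
#' @param input An [input_policy()].
#' @param hemodilution A [hemodilution_policy()].
#' @param viability_minimum Viable fraction below which the specimen is
#'   flagged (default 0.75; post-lysis viability in routine practice sits
#'   near 0.9).
#' @return Tibble with one QC row per specimen.
#' @examples
#' bm <- generate_cohort(cohort_config(n_specimens = 100, seed = 2))
#' qc <- assess_specimens(bm)
#' dplyr::count(qc, hemodilution_category)
#' @export
assess_specimens <- function(records,
                             input = input_policy(),
                             hemodilution = hemodilution_policy(),
                             viability_minimum = 0.75) {
  inp <- assess_input(records, input)
  inp |>
    dplyr::mutate(
      mast_fraction = records$mast_cell_events / pmax(inp$analytical_input, 1),
      hemodilution_category = classify_hemodilution(.data$mast_fraction, hemodilution),
      viability_flag = records$viability < viability_minimum
    )
}
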