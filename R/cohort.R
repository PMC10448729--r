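#' Clinical time points and collection routes recognised by mrdflow
#'
#' Specimens are sampled at the standard multiple-myeloma treatment
#' milestones: end of induction, 60-90 days after autologous stem-cell
#' transplant (ASCT), and years 1, 2 and beyond of post-ASCT maintenance.
#' Aspirates are drawn either at the bedside from the iliac crest or under
#' CT guidance.
#'
#' @format Character vectors of level names.
#' @export
mrd_timepoints <- c(
  "post_induction", "post_asct_60_90d", "post_asct_1y",
  "post_asct_2y", "post_asct_gt2y"
)

#' @rdname mrd_timepoints
#' @export
mrd_routes <- c("bedside_iliac", "ct_guided")

tp_map <- function(values) stats::setNames(as.list(values), mrd_timepoints)

#' Configuration for the synthetic MRD cohort generator
#'
#' Defines the statistical structure of a simulated stream of bone-marrow
#' aspirates submitted for MRD testing by next-generation flow cytometry.
#' Defaults reproduce a large single-institution cohort: mean cellularity
#' 11.5 +/- 7.7 x 10^6 cells/mL, post-lysis viability 90.9 +/- 9%, mast-cell
#' content rising from ~0.004% early after therapy to ~0.015% during late
#' maintenance, a zero-inflated log-normal disease burden with median 0.0059%
#' post-induction falling to 0.0005% just after transplant, and heavier
#' hemodilution for CT-guided than bedside collections.
#'
#' All fractions are dimensionless (not percent). `spill_*` parameters give
#' the share of each marrow-resident population that also circulates in
#' peripheral blood, so hemodilution depletes mast cells completely,
#' normal plasma cells almost completely, and malignant plasma cells least
#' (they adhere to the marrow matrix); the generator requires
#' `spill_mast <= spill_npc <= spill_mm`.
#'
#' @param n_specimens Number of specimens to simulate.
#' @param seed Integer seed; every draw in [generate_cohort()] is derived
#'   from it.
#' @param timepoint_weights Named probabilities over [mrd_timepoints];
#'   must sum to 1.
#' @param route_weights Named probabilities over [mrd_routes].
#' @param cellularity_mean,cellularity_sd Post-lysis nucleated-cell
#'   concentration of the aspirate, cells/mL (log-normal, moment matched).
#' @param viability_mean,viability_sd Post-lysis viable fraction
#'   (normal, clipped to (0, 1]).
#' @param mast_mean_by_timepoint,mast_sd_by_timepoint Named lists of the
#'   undiluted marrow mast-cell fraction per time point (log-normal).
#' @param burden_median_by_timepoint Named list of the median nonzero
#'   MM-PC fraction per time point.
#' @param burden_log_sd Log-scale SD of the nonzero burden distribution.
#' @param mrd_negative_prob_by_timepoint Named list of structural-zero
#'   (true MRD-negative) probabilities per time point.
#' @param npc_mean,npc_sd Undiluted normal plasma-cell fraction
#'   (log-normal).
#' @param dilution_beta_params_by_route Named list of `c(a, b)` Beta
#'   parameters for the peripheral-blood dilution fraction per route.
#' @param spill_mm,spill_npc,spill_mast Blood spill-over fractions in
#'   [0, 1], ordered `spill_mast <= spill_npc <= spill_mm`.
#' @param acquisition_efficiency_range Uniform range of the fraction of
#'   stained cells actually acquired as events per tube.
#' @param volume_mean_ml,volume_sd_ml Aspirate volume (normal, clipped at
#'   2 mL: two 2-3 mL syringes are pooled).
#' @param stain_target_cells Recommended staining input (cells across both
#'   tubes).
#' @param daratumumab_prob Probability a specimen comes from a patient with
#'   anti-CD38 exposure within 12 months (flag only; no effect on counts).
#'
#' @return A list of class `mrd_cohort_config`.
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_specimens = 556,
                          seed = 1L,
                          timepoint_weights = tp_map(c(157, 165, 105, 61, 68) / 556),
                          route_weights = list(bedside_iliac = 497 / 556, ct_guided = 59 / 556),
                          cellularity_mean = 11.5e6,
                          cellularity_sd = 7.7e6,
                          viability_mean = 0.909,
                          viability_sd = 0.09,
                          mast_mean_by_timepoint = tp_map(c(3.8e-5, 3.8e-5, 1.30e-4, 1.55e-4, 1.55e-4)),
                          mast_sd_by_timepoint = tp_map(c(5.6e-5, 5.6e-5, 6.5e-5, 1.6e-4, 1.6e-4)),
                          burden_median_by_timepoint = tp_map(c(5.9e-5, 5e-6, 7e-6, 1.4e-5, 2.8e-5)),
                          burden_log_sd = 2.0,
                          mrd_negative_prob_by_timepoint = tp_map(c(0.24, 0.35, 0.35, 0.30, 0.25)),
                          npc_mean = 2.5e-3,
                          npc_sd = 2.0e-3,
                          dilution_beta_params_by_route = list(
                            bedside_iliac = c(0.7, 4.0), ct_guided = c(2.5, 1.8)
                          ),
                          spill_mm = 0.35,
                          spill_npc = 0.05,
                          spill_mast = 0,
                          acquisition_efficiency_range = c(0.6, 0.95),
                          volume_mean_ml = 5.0,
                          volume_sd_ml = 1.3,
                          stain_target_cells = 20e6,
                          daratumumab_prob = 29 / 307) {
  cfg <- list(
    n_specimens = n_specimens, seed = seed,
    timepoint_weights = timepoint_weights, route_weights = route_weights,
    cellularity_mean = cellularity_mean, cellularity_sd = cellularity_sd,
    viability_mean = viability_mean, viability_sd = viability_sd,
    mast_mean_by_timepoint = mast_mean_by_timepoint,
    mast_sd_by_timepoint = mast_sd_by_timepoint,
    burden_median_by_timepoint = burden_median_by_timepoint,
    burden_log_sd = burden_log_sd,
    mrd_negative_prob_by_timepoint = mrd_negative_prob_by_timepoint,
    npc_mean = npc_mean, npc_sd = npc_sd,
    dilution_beta_params_by_route = dilution_beta_params_by_route,
    spill_mm = spill_mm, spill_npc = spill_npc, spill_mast = spill_mast,
    acquisition_efficiency_range = acquisition_efficiency_range,
    volume_mean_ml = volume_mean_ml, volume_sd_ml = volume_sd_ml,
    stain_target_cells = stain_target_cells,
    daratumumab_prob = daratumumab_prob
  )
  class(cfg) <- "mrd_cohort_config"
  validate_cohort_config(cfg)
}

#' @export
print.mrd_cohort_config <- function(x, ...) {
  cat("<mrd_cohort_config>\n")
  cat(sprintf("  n_specimens: %d   seed: %d\n", x$n_specimens, as.integer(x$seed)))
  cat(sprintf(
    "  cellularity: %.3g +/- %.3g cells/mL   viability: %.3f +/- %.3f\n",
    x$cellularity_mean, x$cellularity_sd, x$viability_mean, x$viability_sd
  ))
  cat(sprintf(
    "  spills (mast/npc/mm): %.2f / %.2f / %.2f   burden_log_sd: %.2f\n",
    x$spill_mast, x$spill_npc, x$spill_mm, x$burden_log_sd
  ))
  invisible(x)
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("Invalid generator config: field `%s` %s.", field, msg),
      call. = FALSE
    )
  }
  if (!is.numeric(cfg$n_specimens) || length(cfg$n_specimens) != 1 ||
    cfg$n_specimens < 1 || cfg$n_specimens != floor(cfg$n_specimens)) {
    fail("n_specimens", "must be a positive integer")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) fail("seed", "must be an integer")

  tw <- unlist(cfg$timepoint_weights)
  if (!setequal(names(tw), mrd_timepoints)) {
    fail("timepoint_weights", "must name every known time point")
  }
  if (any(tw < 0 | tw > 1)) fail("timepoint_weights", "must lie in [0, 1]")
  if (abs(sum(tw) - 1) > 1e-9) fail("timepoint_weights", "must sum to 1 (tolerance 1e-9)")

  rw <- unlist(cfg$route_weights)
  if (!setequal(names(rw), mrd_routes)) fail("route_weights", "must name every route")
  if (abs(sum(rw) - 1) > 1e-9) fail("route_weights", "must sum to 1 (tolerance 1e-9)")

  if (cfg$cellularity_mean <= 0) fail("cellularity_mean", "must be > 0")
  if (cfg$cellularity_sd <= 0) fail("cellularity_sd", "must be > 0")
  if (cfg$viability_sd < 0) fail("viability_sd", "must be >= 0")
  if (cfg$viability_mean <= 0 || cfg$viability_mean > 1) {
    fail("viability_mean", "must lie in (0, 1]")
  }
  for (field in c(
    "mast_mean_by_timepoint", "mast_sd_by_timepoint",
    "burden_median_by_timepoint", "mrd_negative_prob_by_timepoint"
  )) {
    v <- unlist(cfg[[field]])
    if (!setequal(names(v), mrd_timepoints)) fail(field, "must name every known time point")
    if (any(v < 0)) fail(field, "must be non-negative")
  }
  zp <- unlist(cfg$mrd_negative_prob_by_timepoint)
  if (any(zp > 1)) fail("mrd_negative_prob_by_timepoint", "must lie in [0, 1]")
  if (cfg$burden_log_sd < 0) fail("burden_log_sd", "must be >= 0")
  if (cfg$npc_mean <= 0 || cfg$npc_sd < 0) fail("npc_mean", "and npc_sd must be positive")

  db <- cfg$dilution_beta_params_by_route
  if (!setequal(names(db), mrd_routes)) {
    fail("dilution_beta_params_by_route", "must name every route")
  }
  if (any(vapply(db, function(p) length(p) != 2 || any(p <= 0), logical(1)))) {
    fail("dilution_beta_params_by_route", "entries must be positive (a, b) pairs")
  }

  for (field in c("spill_mm", "spill_npc", "spill_mast")) {
    if (cfg[[field]] < 0 || cfg[[field]] > 1) fail(field, "must lie in [0, 1]")
  }
  if (!(cfg$spill_mast <= cfg$spill_npc && cfg$spill_npc <= cfg$spill_mm)) {
    fail("spill_mast", "must satisfy spill_mast <= spill_npc <= spill_mm")
  }
  ae <- cfg$acquisition_efficiency_range
  if (length(ae) != 2 || any(ae <= 0 | ae > 1) || ae[1] > ae[2]) {
    fail("acquisition_efficiency_range", "must be an increasing pair in (0, 1]")
  }
  if (cfg$volume_mean_ml <= 0 || cfg$volume_sd_ml < 0) {
    fail("volume_mean_ml", "and volume_sd_ml must be positive")
  }
  if (cfg$stain_target_cells <= 0) fail("stain_target_cells", "must be > 0")
  check_probability(cfg$daratumumab_prob, "daratumumab_prob")
  cfg
}

# log-normal draws moment-matched to an arithmetic mean and SD; the printed
# summaries have SD of the order of (or above) the mean, which rules out a
# normal model for these strictly positive quantities
rlnorm_mm <- function(n, mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Draw disease burden for one clinical time point
#'
#' Disease burden (the MM-PC fraction of nucleated marrow cells) is modelled
#' as zero-inflated log-normal: with the time point's MRD-negative
#' probability the patient carries no residual clone (exact zero), otherwise
#' the burden is log-normal with the configured median and log-scale SD.
#' Draws consume the current RNG state; seed upstream (e.g. via
#' [withr::with_seed()]) for reproducibility.
#'
#' @param timepoint One of [mrd_timepoints].
#' @param n Number of draws.
#' @param config An [cohort_config()] object.
#' @return Numeric vector of fractions in `[0, 1)`.
#' @export
sample_disease_burden <- function(timepoint, n = 1, config = cohort_config()) {
  timepoint <- as.character(timepoint)
  if (length(timepoint) != 1 || !timepoint %in% mrd_timepoints) {
    stop(sprintf(
      "Unknown timepoint '%s'; expected one of %s.",
      paste(timepoint, collapse = ","), paste(mrd_timepoints, collapse = ", ")
    ), call. = FALSE)
  }
  p0 <- config$mrd_negative_prob_by_timepoint[[timepoint]]
  med <- config$burden_median_by_timepoint[[timepoint]]
  zero <- stats::runif(n) < p0
  x <- stats::rlnorm(n, meanlog = log(med), sdlog = config$burden_log_sd)
  x[zero] <- 0
  # a fraction cannot reach 1; truncate the (astronomically rare) overshoot
  pmin(x, 1 - 1e-12)
}

#' Apply the linear marrow/blood mixing model to true cell fractions
#'
#' An aspirate diluted with a proportion `d` of peripheral blood retains
#' `1 - d` parts marrow; blood carries each population at `spill` times its
#' marrow level, so the observed fraction is
#' `true * (1 - d * (1 - spill))`. Mast cells (`spill = 0`) are fully
#' depleted in proportion to `d`; malignant plasma cells, with the largest
#' spill, are depleted least.
#'
#' @param true_fractions Named list or data frame with elements `mm`, `npc`
#'   and `mast` (true undiluted fractions; vectors allowed).
#' @param d Dilution fraction(s) in `[0, 1]` (0 = pure marrow, 1 = pure
#'   blood).
#' @param spills Named list with elements `mm`, `npc`, `mast` in `[0, 1]`.
#' @return A tibble with columns `mm`, `npc`, `mast` of observed fractions.
#' @examples
#' apply_hemodilution(list(mm = 1e-5, npc = 2e-3, mast = 8e-5), d = 0.5)
#' @export
apply_hemodilution <- function(true_fractions, d,
                               spills = list(mm = 0.35, npc = 0.05, mast = 0)) {
  if (!all(c("mm", "npc", "mast") %in% names(true_fractions))) {
    stop("`true_fractions` must contain elements mm, npc and mast.", call. = FALSE)
  }
  if (!is.numeric(d) || any(d < 0 | d > 1)) {
    stop("Dilution `d` must lie in [0, 1].", call. = FALSE)
  }
  for (pop in c("mm", "npc", "mast")) check_probability(spills[[pop]], paste0("spill_", pop))
  tibble::tibble(
    mm = true_fractions$mm * (1 - d * (1 - spills$mm)),
    npc = true_fractions$npc * (1 - d * (1 - spills$npc)),
    mast = true_fractions$mast * (1 - d * (1 - spills$mast))
  )
}

# exact multinomial event counts via sequential binomial conditioning
draw_event_counts <- function(n_events, p_mm, p_npc, p_mast) {
  mm <- stats::rbinom(length(n_events), n_events, p_mm)
  npc <- stats::rbinom(length(n_events), n_events - mm, pmin(p_npc / (1 - p_mm), 1))
  mast <- stats::rbinom(
    length(n_events), n_events - mm - npc,
    pmin(p_mast / (1 - p_mm - p_npc), 1)
  )
  list(mm = mm, npc = npc, mast = mast)
}

#' Generate a synthetic MRD specimen cohort
#'
#' Simulates `config$n_specimens` bone-marrow aspirates submitted for MRD
#' testing by next-generation flow: clinical time point and collection route
#' are drawn from the configured weights; cellularity, viability and the
#' undiluted mast-cell / normal-PC / MM-PC fractions from moment-matched
#' log-normals (burden zero-inflated); a latent peripheral-blood dilution
#' from the route's Beta law; observed fractions through
#' [apply_hemodilution()]; and per-tube event counts as multinomial draws
#' given the acquired events. Output is bitwise reproducible for a fixed
#' config (the seed lives in the config).
#'
#' @param config An [cohort_config()] object.
#' @return A tibble with one row per specimen (see the package vignette for
#'   the column dictionary). The latent ground truth (true dilution and
#'   undiluted fractions) is attached as a sidecar tibble in
#'   `attr(, "truth")` and retrieved with [cohort_truth()]; it is not part
#'   of the specimen schema because a real laboratory never observes it.
#' @examples
#' bm <- generate_cohort(cohort_config(n_specimens = 50, seed = 7))
#' dplyr::count(bm, timepoint)
#' @export
generate_cohort <- function(config = cohort_config()) {
  config <- validate_cohort_config(config)
  n <- config$n_specimens
  withr::local_seed(as.integer(config$seed))

  timepoint <- sample(mrd_timepoints, n,
    replace = TRUE,
    prob = unlist(config$timepoint_weights)[mrd_timepoints]
  )
  route <- sample(mrd_routes, n,
    replace = TRUE,
    prob = unlist(config$route_weights)[mrd_routes]
  )
  # ~55% as many patients as specimens: about half are tested more than once
  patient_pool <- sprintf("P%04d", seq_len(max(1, ceiling(n * 0.55))))
  patient_id <- sample(patient_pool, n, replace = TRUE)

  cellularity <- rlnorm_mm(n, config$cellularity_mean, config$cellularity_sd)
  viability <- pmin(1, pmax(1e-3, stats::rnorm(n, config$viability_mean, config$viability_sd)))
  volume <- pmax(2, stats::rnorm(n, config$volume_mean_ml, config$volume_sd_ml))

  # configured mast summaries describe the observed (diluted) cohort; divide
  # out the config-implied mean depletion to get undiluted marrow levels
  rw <- unlist(config$route_weights)[mrd_routes]
  mean_d <- vapply(
    config$dilution_beta_params_by_route[mrd_routes],
    function(p) p[1] / (p[1] + p[2]), numeric(1)
  )
  mast_depletion <- sum(rw * (1 - mean_d * (1 - config$spill_mast)))
  true_mast <- rlnorm_mm(
    n, unlist(config$mast_mean_by_timepoint)[timepoint] / mast_depletion,
    unlist(config$mast_sd_by_timepoint)[timepoint] / mast_depletion
  )
  true_npc <- rlnorm_mm(n, config$npc_mean, config$npc_sd)
  true_mm <- unname(vapply(
    timepoint,
    function(tp) sample_disease_burden(tp, 1, config),
    numeric(1)
  ))

  ab <- config$dilution_beta_params_by_route
  a <- vapply(route, function(r) ab[[r]][1], numeric(1))
  b <- vapply(route, function(r) ab[[r]][2], numeric(1))
  d <- stats::rbeta(n, a, b)

  obs <- apply_hemodilution(
    list(mm = true_mm, npc = true_npc, mast = true_mast), d,
    spills = list(mm = config$spill_mm, npc = config$spill_npc, mast = config$spill_mast)
  )

  available <- volume * cellularity
  stained <- floor(pmin(config$stain_target_cells, available))
  eff_a <- stats::runif(n, config$acquisition_efficiency_range[1], config$acquisition_efficiency_range[2])
  eff_b <- stats::runif(n, config$acquisition_efficiency_range[1], config$acquisition_efficiency_range[2])
  acquired_a <- round(pmin(stained / 2, eff_a * stained / 2))
  acquired_b <- round(pmin(stained / 2, eff_b * stained / 2))

  counts <- draw_event_counts(acquired_a + acquired_b, obs$mm, obs$npc, obs$mast)
  dara <- stats::runif(n) < config$daratumumab_prob

  specimens <- tibble::tibble(
    specimen_id = sprintf("S%05d", seq_len(n)),
    patient_id = patient_id,
    timepoint = factor(timepoint, levels = mrd_timepoints),
    collection_route = factor(route, levels = mrd_routes),
    aspirate_volume_ml = volume,
    cellularity_per_ml = cellularity,
    viability = viability,
    stained_cells = stained,
    acquired_events_tube_a = acquired_a,
    acquired_events_tube_b = acquired_b,
    mm_pc_events = counts$mm,
    n_pc_events = counts$npc,
    mast_cell_events = counts$mast,
    daratumumab_exposed = dara
  )
  truth <- tibble::tibble(
    specimen_id = specimens$specimen_id,
    true_dilution = d,
    true_mm_fraction = true_mm,
    true_npc_fraction = true_npc,
    true_mast_fraction = true_mast
  )
  attr(specimens, "truth") <- truth
  specimens
}

#' Extract the latent ground-truth sidecar of a synthetic cohort
#'
#' @param cohort A tibble produced by [generate_cohort()].
#' @return Tibble with `specimen_id`, `true_dilution` and the undiluted
#'   `true_*_fraction` columns.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) {
    stop("This cohort carries no ground-truth sidecar (real data, or dropped by a transform).",
      call. = FALSE
    )
  }
  truth
}

#' Read and write specimen tables
#'
#' Specimen tables are exchanged as headered RFC-4180 CSV, one row per
#' specimen. `write_cohort()` also writes the ground-truth sidecar next to
#' the main table when present; `read_cohort()` re-attaches a sidecar if
#' given.
#'
#' @param cohort Specimen tibble.
#' @param path Output CSV path.
#' @param truth_path Optional path for the ground-truth sidecar.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the specimen tibble.
#' @export
write_cohort <- function(cohort, path, truth_path = NULL) {
  readr::write_csv(cohort, path)
  if (!is.null(truth_path)) {
    readr::write_csv(cohort_truth(cohort), truth_path)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path, truth_path = NULL) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  cohort$timepoint <- factor(cohort$timepoint, levels = mrd_timepoints)
  cohort$collection_route <- factor(cohort$collection_route, levels = mrd_routes)
  if (!is.null(truth_path)) {
    attr(cohort, "truth") <- readr::read_csv(truth_path, show_col_types = FALSE)
  }
  cohort
}

#' Serialise a generator configuration to YAML or JSON
#'
#' @param config An [cohort_config()] object.
#' @param path Destination ending in `.yaml`/`.yml` or `.json`.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a validated [cohort_config()].
#' @export
write_config <- function(config, path) {
  config <- validate_cohort_config(config)
  plain <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path, precision = 15)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  raw$dilution_beta_params_by_route <- lapply(raw$dilution_beta_params_by_route, unlist)
  raw$acquisition_efficiency_range <- unlist(raw$acquisition_efficiency_range)
  raw$timepoint_weights <- as.list(unlist(raw$timepoint_weights))
  raw$route_weights <- as.list(unlist(raw$route_weights))
  for (f in c(
    "mast_mean_by_timepoint", "mast_sd_by_timepoint",
    "burden_median_by_timepoint", "mrd_negative_prob_by_timepoint"
  )) {
    raw[[f]] <- as.list(unlist(raw[[f]]))
  }
  do.call(cohort_config, raw[setdiff(names(raw), character(0))])
}
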