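mrd_caveats <- c(
  low_input = "low analytical input; sensitivity reduced",
  marginal_input = "marginal stain input",
  hemodilution = "hemodiluted; burden may be underestimated"
)

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

check_alignment <- function(records, other, other_name) {
  missing_qc <- setdiff(records$specimen_id, other$specimen_id)
  extra_qc <- setdiff(other$specimen_id, records$specimen_id)
  if (length(missing_qc) || length(extra_qc)) {
    stop(sprintf(
      "`records` and `%s` do not align; orphan specimen ids: %s.",
      other_name,
      paste(utils::head(c(missing_qc, extra_qc), 10), collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Summarise a cohort's adequacy and MRD rates
#'
#' Counts specimens per hemodilution and input category, derives the
#' suboptimal percentage, and tabulates MRD positivity per threshold plus
#' negativity per time point and threshold and the median burden per time
#' point. All percentages are retained at full precision; the print method
#' rounds half-up to one decimal.
#'
#' @param records Specimen tibble.
#' @param qc QC tibble from [assess_specimens()].
#' @param calls Calls tibble from [call_mrd_cohort()].
#' @return Object of class `mrd_cohort_summary`.
#' @export
summarize_cohort <- function(records, qc, calls) {
  if (nrow(records) == 0) stop("Cannot summarise an empty cohort.", call. = FALSE)
  check_alignment(records, qc, "qc")
  check_alignment(records, calls, "calls")

  n <- nrow(records)
  adequacy_counts <- qc |>
    dplyr::count(category = .data$hemodilution_category, .drop = FALSE)
  input_counts <- qc |>
    dplyr::count(category = .data$input_category, .drop = FALSE)
  pct_suboptimal <-
    100 * adequacy_counts$n[adequacy_counts$category == "suboptimal"] / n

  positivity_by_threshold <- calls |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(
      n = dplyr::n(),
      positivity_rate = 100 * mean(.data$status == "positive"),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$threshold))

  tp <- dplyr::select(records, "specimen_id", "timepoint")
  negativity_by_timepoint <- calls |>
    dplyr::inner_join(tp, by = "specimen_id") |>
    dplyr::group_by(.data$timepoint, .data$threshold) |>
    dplyr::summarise(
      n = dplyr::n(),
      negativity_rate = 100 * mean(.data$status == "negative"),
      .groups = "drop"
    )

  median_burden_by_timepoint <- records |>
    dplyr::mutate(
      mm_pc_fraction = mm_pc_fraction(
        .data$mm_pc_events,
        .data$acquired_events_tube_a + .data$acquired_events_tube_b
      )
    ) |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::summarise(median_burden = stats::median(.data$mm_pc_fraction), .groups = "drop")

  structure(
    list(
      n_specimens = n,
      adequacy_counts = adequacy_counts,
      input_counts = input_counts,
      pct_suboptimal = pct_suboptimal,
      positivity_by_threshold = positivity_by_threshold,
      negativity_by_timepoint = negativity_by_timepoint,
      median_burden_by_timepoint = median_burden_by_timepoint
    ),
    class = "mrd_cohort_summary"
  )
}

#' @export
print.mrd_cohort_summary <- function(x, ...) {
  cat("<mrd_cohort_summary>\n")
  cat(sprintf("  %d specimens\n", x$n_specimens))
  ac <- x$adequacy_counts
  cat(sprintf(
    "  hemodilution: %s (%.1f%% suboptimal)\n",
    paste(sprintf("%s %d", ac$category, ac$n), collapse = ", "),
    round_half_up(x$pct_suboptimal, 1)
  ))
  pt <- x$positivity_by_threshold
  cat("  MRD positivity:",
    paste(sprintf(
      "%.1f%% at %.3g", round_half_up(pt$positivity_rate, 1),
      pt$threshold
    ), collapse = ", "), "\n")
  invisible(x)
}

#' Adequacy-qualified per-specimen MRD reports
#'
#' Applies the clinical reporting rules: a positive call is always reported
#' positive (with caveats for any adequacy problem - detected disease
#' survives a degraded assay); a call that is not evaluable at the
#' requested threshold (effective sensitivity coarser than the threshold)
#' is reported, per laboratory policy, either as negative at the reduced
#' sensitivity actually achieved or as not evaluable; a negative call on a
#' significantly hemodiluted specimen is reported negative at reduced
#' sensitivity; an adequate negative is a plain negative at nominal
#' sensitivity with no caveats.
#'
#' @param records Specimen tibble.
#' @param qc QC tibble from [assess_specimens()].
#' @param calls Calls tibble (one threshold, or several: one report row per
#'   call row).
#' @param negative_policy How to report a specimen whose effective
#'   sensitivity is coarser than the requested threshold:
#'   `"reduced_sensitivity"` (default) or `"not_evaluable"`.
#' @return Tibble with `specimen_id`, `threshold`, `mrd_status`,
#'   `burden_band`, `reported_sensitivity`, `evaluable`, `qc_caveats`
#'   (semicolon-joined; empty string when clean).
#' @export
render_report <- function(records, qc, calls,
                          negative_policy = c("reduced_sensitivity", "not_evaluable")) {
  negative_policy <- match.arg(negative_policy)
  check_alignment(records, qc, "qc")
  check_alignment(records, calls, "calls")

  df <- calls |>
    dplyr::inner_join(
      dplyr::select(
        qc, "specimen_id", "input_category", "analytical_input_ok",
        "revised_lod", "hemodilution_category"
      ),
      by = "specimen_id"
    )

  caveat_low <- !df$analytical_input_ok | !is.na(df$revised_lod)
  caveat_marginal <- df$input_category == "marginal"
  caveat_hemo <- df$hemodilution_category == "suboptimal"
  caveats <- purrr::pmap_chr(
    list(caveat_low, caveat_marginal, caveat_hemo),
    function(lo, mar, hemo) {
      paste(mrd_caveats[c(lo, mar, hemo)], collapse = "; ")
    }
  )

  not_eval_status <- if (negative_policy == "reduced_sensitivity") {
    "negative_reduced_sensitivity"
  } else {
    "not_evaluable"
  }
  status <- dplyr::case_when(
    df$status == "positive" ~ "positive",
    df$status == "not_evaluable" ~ not_eval_status,
    caveat_hemo ~ "negative_reduced_sensitivity",
    .default = "negative"
  )

  tibble::tibble(
    specimen_id = df$specimen_id,
    threshold = df$threshold,
    mrd_status = factor(
      status,
      levels = c(
        "positive", "negative", "negative_reduced_sensitivity",
        "not_evaluable"
      )
    ),
    burden_band = df$burden_band,
    reported_sensitivity = dplyr::coalesce(df$revised_lod, df$threshold),
    evaluable = df$status != "not_evaluable",
    qc_caveats = caveats
  )
}

#' Run the full specimen-adequacy and assay-performance pipeline
#'
#' Generates (or ingests) a cohort, assesses specimen QC, calls MRD at the
#' requested virtual sensitivities, scans targeted sensitivities for the
#' achievable assay sensitivity, summarises the cohort and renders
#' per-specimen reports. With `out_dir` set, all tables are written as CSV
#' plus a machine-readable summary and a manifest (inputs, seed, package
#' version, file checksums); reruns with the same configuration are
#' byte-identical.
#'
#' @param config An [cohort_config()]; ignored when `cohort` is supplied.
#' @param cohort Optional pre-existing specimen tibble (e.g. from
#'   [read_cohort()]).
#' @param thresholds Virtual sensitivities for MRD calls.
#' @param report_threshold Threshold at which per-specimen reports are
#'   rendered (default the finest in `thresholds`).
#' @param grid,bootstrap_reps Passed to [sensitivity_scan()] (the scan is
#'   seeded from the config seed).
#' @param negative_policy Passed to [render_report()].
#' @param out_dir Optional output directory.
#' @return (Invisibly) a list with `cohort`, `truth` (when synthetic),
#'   `qc`, `calls`, `scan`, `summary`, `reports` and `manifest`.
#' @export
run_pipeline <- function(config = cohort_config(),
                         cohort = NULL,
                         thresholds = c(1e-4, 1e-5, 2e-6, 1e-6),
                         report_threshold = min(thresholds),
                         grid = sensitivity_grid(),
                         bootstrap_reps = 200,
                         negative_policy = "reduced_sensitivity",
                         out_dir = NULL) {
  if (any(c(thresholds, grid) < 5e-7)) {
    warning(paste(
      "Requested sensitivity finer than 5e-7, below the resolution at which",
      "a clonal plasma-cell cluster can be reproducibly resolved."
    ), call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
  }
  if (is.null(cohort)) cohort <- stage("generate", generate_cohort(config))
  truth <- attr(cohort, "truth")
  qc <- stage("qc", assess_specimens(cohort))
  calls <- stage("call", call_mrd_cohort(cohort, qc, thresholds = thresholds))
  scan <- stage("performance", sensitivity_scan(
    cohort,
    grid = grid, bootstrap_reps = bootstrap_reps, seed = config$seed
  ))
  summary <- stage("summarize", summarize_cohort(cohort, qc, calls))
  reports <- stage("report", render_report(
    cohort, qc,
    dplyr::filter(calls, .data$threshold == report_threshold),
    negative_policy = negative_policy
  ))

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(out_dir, c(
      cohort = "cohort.csv", qc = "qc.csv", calls = "calls.csv",
      scan = "scan.csv", reports = "reports.csv", summary = "summary.json"
    ))
    names(paths) <- c("cohort", "qc", "calls", "scan", "reports", "summary")
    readr::write_csv(cohort, paths["cohort"])
    if (!is.null(truth)) {
      paths <- c(paths, truth = file.path(out_dir, "truth.csv"))
      readr::write_csv(truth, paths["truth"])
    }
    readr::write_csv(qc, paths["qc"])
    readr::write_csv(calls, paths["calls"])
    readr::write_csv(scan$results, paths["scan"])
    readr::write_csv(reports, paths["reports"])
    jsonlite::write_json(
      list(
        schema = "mrdflow/cohort-summary/v1",
        n_specimens = summary$n_specimens,
        adequacy_counts = summary$adequacy_counts,
        pct_suboptimal = summary$pct_suboptimal,
        positivity_by_threshold = summary$positivity_by_threshold,
        negativity_by_timepoint = summary$negativity_by_timepoint,
        median_burden_by_timepoint = summary$median_burden_by_timepoint,
        achievable_sensitivity = scan$achievable_sensitivity
      ),
      paths["summary"],
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    manifest_path <- file.path(out_dir, "manifest.json")
    manifest <- list(
      schema = "mrdflow/manifest/v1",
      package = "mrdflow",
      version = as.character(utils::packageVersion("mrdflow")),
      seed = as.integer(config$seed),
      n_specimens = nrow(cohort),
      thresholds = thresholds,
      bootstrap_reps = bootstrap_reps,
      files = as.list(stats::setNames(
        unname(tools::md5sum(unname(paths))), basename(unname(paths))
      ))
    )
    jsonlite::write_json(manifest, manifest_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }

  invisible(list(
    cohort = cohort, truth = truth, qc = qc, calls = calls, scan = scan,
    summary = summary, reports = reports, manifest = manifest
  ))
}
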