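#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy blank statistics
#'
#' @param x An `mrd_blank_stats` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble of term/estimate pairs (blank mean and
#'   SD, LOB, LOD, LLOQ). `glance()`: a one-row tibble.
#' @method tidy mrd_blank_stats
#' @export
tidy.mrd_blank_stats <- function(x, ...) {
  tibble::tibble(
    term = c("v_mean", "v_sd", "lob", "lod", "lloq"),
    estimate = c(x$v_mean, x$v_sd, x$lob, x$lod, x$lloq)
  )
}

#' @rdname tidy.mrd_blank_stats
#' @method glance mrd_blank_stats
#' @export
glance.mrd_blank_stats <- function(x, ...) {
  tibble::tibble(
    threshold = x$threshold, n_blank = x$n_blank,
    v_mean = x$v_mean, v_sd = x$v_sd,
    lob = x$lob, lod = x$lod, lloq = x$lloq
  )
}

#' Tidy a sensitivity scan
#'
#' @param x An `mrd_sensitivity_scan` object.
#' @param ... Unused.
#' @return `tidy()`: the per-threshold results tibble (threshold, blank
#'   count, blank moments, LOB/virtual LOD/LLOQ, RMSE). `glance()`: a
#'   one-row tibble with the selected achievable sensitivity.
#' @method tidy mrd_sensitivity_scan
#' @export
tidy.mrd_sensitivity_scan <- function(x, ...) {
  x$results
}

#' @rdname tidy.mrd_sensitivity_scan
#' @method glance mrd_sensitivity_scan
#' @export
glance.mrd_sensitivity_scan <- function(x, ...) {
  tibble::tibble(
    n_thresholds = nrow(x$results),
    n_usable = sum(!is.na(x$results$rmse)),
    bootstrap_reps = x$bootstrap_reps,
    seed = x$seed,
    achievable_sensitivity = x$achievable_sensitivity
  )
}

#' Tidy a cohort summary
#'
#' @param x An `mrd_cohort_summary` object.
#' @param ... Unused.
#' @return `tidy()`: a long tibble of cohort rates (one row per statistic
#'   and group). `glance()`: a one-row overview.
#' @method tidy mrd_cohort_summary
#' @export
tidy.mrd_cohort_summary <- function(x, ...) {
  dplyr::bind_rows(
    x$adequacy_counts |>
      dplyr::transmute(
        statistic = "hemodilution_share",
        group = as.character(.data$category),
        threshold = NA_real_,
        value = 100 * .data$n / x$n_specimens
      ),
    x$positivity_by_threshold |>
      dplyr::transmute(
        statistic = "positivity_rate",
        group = NA_character_,
        threshold = .data$threshold,
        value = .data$positivity_rate
      ),
    x$negativity_by_timepoint |>
      dplyr::transmute(
        statistic = "negativity_rate",
        group = as.character(.data$timepoint),
        threshold = .data$threshold,
        value = .data$negativity_rate
      ),
    x$median_burden_by_timepoint |>
      dplyr::transmute(
        statistic = "median_burden",
        group = as.character(.data$timepoint),
        threshold = NA_real_,
        value = .data$median_burden
      )
  )
}

#' @rdname tidy.mrd_cohort_summary
#' @method glance mrd_cohort_summary
#' @export
glance.mrd_cohort_summary <- function(x, ...) {
  ac <- stats::setNames(x$adequacy_counts$n, x$adequacy_counts$category)
  tibble::tibble(
    n_specimens = x$n_specimens,
    n_adequate = ac[["adequate"]],
    n_marginal = ac[["marginal"]],
    n_suboptimal = ac[["suboptimal"]],
    pct_suboptimal = x$pct_suboptimal
  )
}

#' Plot a sensitivity scan
#'
#' Two stacked views of the virtual-sensitivity scan: the calculated
#' virtual LOD against its target (with the identity line a perfectly
#' tracking assay would follow) and the bootstrap RMSE per target, with the
#' selected achievable sensitivity marked.
#'
#' @param object An `mrd_sensitivity_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrd_sensitivity_scan
#' @export
autoplot.mrd_sensitivity_scan <- function(object, ...) {
  res <- tidyr::pivot_longer(
    dplyr::select(object$results, "threshold", "vlod", "rmse"),
    c("vlod", "rmse"),
    names_to = "panel", values_to = "value"
  )
  res$panel <- factor(res$panel,
    levels = c("vlod", "rmse"),
    labels = c("virtual LOD", "bootstrap RMSE")
  )
  ggplot2::ggplot(res, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_abline(
      data = data.frame(panel = factor("virtual LOD",
        levels = c("virtual LOD", "bootstrap RMSE")
      )),
      ggplot2::aes(intercept = 0, slope = 1),
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_vline(
      xintercept = object$achievable_sensitivity,
      linetype = "dotted", colour = "firebrick"
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$panel), ncol = 1, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "targeted virtual sensitivity (fraction of nucleated cells)",
      y = NULL,
      title = "Virtual LOD scan",
      subtitle = "dotted line: selected achievable sensitivity"
    )
}

#' Plot cohort MRD positivity by virtual sensitivity
#'
#' @param object An `mrd_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mrd_cohort_summary
#' @export
autoplot.mrd_cohort_summary <- function(object, ...) {
  df <- object$positivity_by_threshold
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = factor(format(.data$threshold)), y = .data$positivity_rate)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "virtual sensitivity threshold",
      y = "MRD positivity (%)",
      title = "MRD positivity by virtual sensitivity"
    )
}

#' Mast-cell content by clinical time point
#'
#' Box plot of observed mast-cell fractions per time point with the
#' per-time-point lower limit of normal overlaid; the conventional
#' adequacy check for hemodilution.
#'
#' @param records Specimen tibble.
#' @param qc QC tibble from [assess_specimens()].
#' @return A ggplot object.
#' @export
plot_mast_by_timepoint <- function(records, qc) {
  df <- dplyr::inner_join(
    dplyr::select(records, "specimen_id", "timepoint"),
    dplyr::select(qc, "specimen_id", "mast_fraction"),
    by = "specimen_id"
  )
  lln <- compute_lln(df, mast_fraction, timepoint)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timepoint, y = .data$mast_fraction)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(
      data = lln, ggplot2::aes(y = .data$lln),
      colour = "firebrick", shape = 95, size = 8
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = NULL, y = "mast-cell fraction of nucleated events",
      title = "Hemodilution proxy by clinical time point",
      subtitle = "red dash: lower limit of normal (mean - 1 SD)"
    )
}
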