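#' Kaplan-Meier step curves
#'
#' @param x A [km_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(x, ...) {
  curve <- tidy(x) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = max(.x$n_risk), n_event = 0L,
                     survival = 1, conf_low = 1, conf_high = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(curve,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Progression-free survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.km_fit
#' @export
plot_km <- function(x, ...) autoplot(x, ...)

#' Waterfall plot of best percentage change in tumor burden
#'
#' One bar per patient: the best (most negative) percent change of the
#' target-lesion diameter sum from baseline, sorted decreasing, with the
#' RECIST partial-response (-30%) and progression (+20%) thresholds drawn.
#' Bars can be coloured by a patient-level flag such as Amp11q13 status.
#'
#' @param assessments Per-timepoint tibble from [recist_assessments()].
#' @param patients Optional patient table with `patient_id` and the
#'   `colour_by` column.
#' @param colour_by Column of `patients` used as fill.
#' @return A ggplot object.
#' @export
plot_waterfall <- function(assessments, patients = NULL,
                           colour_by = "amp11q13") {
  best <- assessments |>
    dplyr::filter(.data$time_months > 0,
                  !is.na(.data$pct_change_baseline)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(best_change = min(.data$pct_change_baseline),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$best_change)) |>
    dplyr::mutate(rank = dplyr::row_number())
  mapping <- ggplot2::aes(.data$rank, .data$best_change)
  if (!is.null(patients) && colour_by %in% names(patients)) {
    best <- dplyr::left_join(
      best, dplyr::select(patients, "patient_id",
                          dplyr::all_of(colour_by)), by = "patient_id")
    mapping <- ggplot2::aes(.data$rank, .data$best_change,
                            fill = .data[[colour_by]])
  }
  ggplot2::ggplot(best, mapping) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-30, 20), linetype = "dashed") +
    ggplot2::labs(x = "Patients", y = "Best change from baseline (%)") +
    ggplot2::theme_minimal()
}

#' Spider plot of simulated tumor-burden trajectories
#'
#' @param object A `synthetic_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synthetic_cohort
#' @export
autoplot.synthetic_cohort <- function(object, ...) {
  burden <- tumor_burden_series(object$lesions)
  ggplot2::ggplot(burden,
                  ggplot2::aes(.data$time_months, .data$s_mm,
                               group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Months from therapy start",
                  y = "Sum of longest diameters (mm)") +
    ggplot2::theme_minimal()
}
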