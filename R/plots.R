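#' Plot normalised adaptation curves
#'
#' Mean previous-block-normalised start time (with SEM ribbon) per
#' post-transition trial, faceted by estimator, coloured by transition
#' direction. The dashed line at 100% is the previous-block baseline.
#'
#' @param object An `sfi_adaptation_curves` tibble
#'   (see [adaptation_curves()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sfi_adaptation_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$post_trial, y = .data$mean_pct, colour = .data$direction,
    fill = .data$direction
  )) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_pct - .data$sem_pct,
      ymax = .data$mean_pct + .data$sem_pct
    ), alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::scale_x_continuous(breaks = function(l) {
      seq(ceiling(l[1]), floor(l[2]))
    }) +
    ggplot2::labs(
      x = "trial after block transition",
      y = "start time (% of previous-block mean)",
      colour = "transition", fill = "transition"
    ) +
    ggplot2::theme_minimal()
}

#' Plot correlation build-up after block transitions
#'
#' R-squared of start time against FI duration at each post-transition
#' trial, per estimator.
#'
#' @param object An `sfi_correlations` tibble
#'   (see [post_transition_correlations()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sfi_correlations <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$post_trial, y = .data$r_squared, colour = .data$metric
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "trial after block transition",
      y = expression(R^2 ~ "(start time vs FI duration)"),
      colour = "estimator"
    ) +
    ggplot2::theme_minimal()
}

#' Raster plot of a session's pressing
#'
#' One row per trial (in session order), each press a tick, the reward a
#' point, with optional start-time estimates overlaid. The visual analogue
#' of per-trial press rasters used to inspect sFI behaviour.
#'
#' @param trials A trials tibble for a single session.
#' @param start_times Optional matching start-time table from
#'   [estimate_start_times()]; estimates are overlaid as coloured points.
#' @return A ggplot object.
#' @export
plot_session_raster <- function(trials, start_times = NULL) {
  check_trials(trials)
  df <- trials |>
    dplyr::mutate(trial = dplyr::row_number()) |>
    tidyr::unnest_longer("press_times", values_to = "time")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$trial)) +
    ggplot2::geom_point(shape = "|", size = 2) +
    ggplot2::geom_point(
      data = dplyr::mutate(trials, trial = dplyr::row_number()),
      ggplot2::aes(x = .data$reward_time), colour = "black", size = 1
    ) +
    ggplot2::geom_step(
      data = dplyr::mutate(trials, trial = dplyr::row_number()),
      ggplot2::aes(x = .data$fi_duration), direction = "vh",
      colour = "grey40"
    ) +
    ggplot2::labs(x = "time in trial (s)", y = "trial") +
    ggplot2::theme_minimal()
  if (!is.null(start_times)) {
    st <- start_times |>
      dplyr::mutate(trial = dplyr::row_number()) |>
      tidyr::pivot_longer(dplyr::any_of(start_metric_names()),
                          names_to = "estimator", values_to = "time") |>
      dplyr::filter(!is.na(.data$time))
    p <- p + ggplot2::geom_point(
      data = st,
      ggplot2::aes(x = .data$time, colour = .data$estimator), size = 1.2
    )
  }
  p
}
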