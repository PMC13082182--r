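# Diagnostic plots. The pipeline's presentation figures are out of scope;
# these cover what an analyst needs to sanity-check a run.

#' Plot a weekly heart-rate profile with its fitted sine curve
#'
#' @param profile Single-participant output of [aggregate_weekly_profile()].
#' @param fit Optional one-row [fit_sine()] result to overlay.
#' @return A ggplot object.
#' @export
plot_weekly_profile <- function(profile, fit = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$bin_start / 60, y = .data$mean_hr)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::labs(x = "Time of week (h from Sunday 00:00)",
                  y = "Mean heart rate (bpm)")
  if (!is.null(fit) && isTRUE(fit$fit_ok[1])) {
    grid <- tibble::tibble(t = seq(0, 10075, by = 5))
    grid$hr <- sine_predict(fit$A[1], fit$phi[1], fit$b[1], grid$t)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$t / 60, y = .data$hr),
                                colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a goodness-of-fit threshold scan
#'
#' Retention rate and Youden index against the candidate threshold, with the
#' selected threshold marked.
#'
#' @param object An `hrp_threshold_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hrp_threshold_scan <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("retention", "youden"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "selected"),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(R^2 ~ "threshold"), y = NULL)
}

#' Histogram of cohort heart-rate phases
#'
#' @param cohort Cohort table with `phi` and `included`.
#' @param binwidth Bin width in hours (default 0.5).
#' @return A ggplot object.
#' @export
plot_phase_distribution <- function(cohort, binwidth = 0.5) {
  df <- cohort |> dplyr::filter(.data$included)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "steelblue",
                            colour = "white") +
    ggplot2::labs(x = "Heart-rate phase (h)", y = "Participants")
}
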