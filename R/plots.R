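#' Plot the pooled-area traces of a trial
#'
#' One facet per recording area, activity against time within the 2-s
#' window; the dopamine trace can be added on its own (0-0.5) scale facet.
#'
#' @param trial A `tic_trial`.
#' @param include_da Add the dopamine unit facet.
#' @return A ggplot object.
#' @export
plot_trial <- function(trial, include_da = FALSE) {
  df <- tidy(trial, pooled = TRUE, include_da = include_da)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$activity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~area, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "activity",
                  title = if (is.na(trial$label)) NULL
                          else paste0("trial label: ", trial$label)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_trial
#' @param object,... `autoplot()` arguments (`object` is the trial).
#' @export
autoplot.tic_trial <- function(object, ...) plot_trial(object, ...)

#' Plot TIC vs NO-TIC peak amplitudes per area
#'
#' Mean and standard deviation of the peak amplitude per area and
#' movement state.
#'
#' @param tbl A [peak_table()].
#' @return A ggplot object.
#' @export
plot_peaks <- function(tbl) {
  sm <- tbl |>
    dplyr::group_by(.data$area, .data$state) |>
    dplyr::summarise(mean = mean(.data$peak), sd = stats::sd(.data$peak),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$area, y = .data$mean,
                                   colour = .data$state,
                                   group = .data$state)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::labs(x = NULL, y = "peak amplitude (activity)",
                  colour = "state") +
    ggplot2::theme_minimal()
}

#' Plot onset delays relative to M1
#'
#' @param tbl A [latency_table()].
#' @return A ggplot object.
#' @export
plot_latency <- function(tbl) {
  sm <- tbl |>
    dplyr::group_by(.data$area) |>
    dplyr::summarise(mean = mean(.data$delay_s), sd = stats::sd(.data$delay_s),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$area, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "onset delay vs M1 (s, positive = leads)") +
    ggplot2::theme_minimal()
}

#' Plot the dopamine dose-response
#'
#' Mean tic count (with SD bars) per dopamine burst height.
#'
#' @param counts A [dose_response()] table.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(counts) {
  sm <- counts |>
    dplyr::group_by(.data$da_height) |>
    dplyr::summarise(mean = mean(.data$n_tics), sd = stats::sd(.data$n_tics),
                     .groups = "drop")
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$da_height, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "dopamine burst height", y = "tics per subject") +
    ggplot2::theme_minimal()
}

#' Plot the per-generation best fitting error
#'
#' @param fit A `tic_fit`.
#' @return A ggplot object.
#' @export
plot_fit_progress <- function(fit) {
  ggplot2::ggplot(fit$generations,
                  ggplot2::aes(x = .data$generation, y = .data$best_error)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "generation", y = "best normalised error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
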