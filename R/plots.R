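# ggplot2 displays for the main result types.

#' Plot tracks translated to the origin (flower plot)
#'
#' @inheritParams filter_tracks
#' @return A ggplot.
#' @export
plot_tracks_at_origin <- function(tracks) {
  dat <- translate_to_origin(tracks)
  ggplot2::ggplot(dat, ggplot2::aes(.data$x_um, .data$y_um,
                                    group = .data$track_id)) +
    ggplot2::geom_path(alpha = 0.4, linewidth = 0.3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Tracks at origin") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_min, .data$msd_um2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.autocorr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$lag_min, .data$mean_cos)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "lag (min)", y = "mean cos θ") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.prw_fit <- function(object, ...) {
  curve <- object$curve
  fitted <- tibble::tibble(
    lag_min = seq(0, max(curve$lag_min), length.out = 200L))
  fitted$msd_um2 <- prw_msd(fitted$lag_min, object$D, object$P)
  ggplot2::ggplot(curve, ggplot2::aes(.data$lag_min, .data$msd_um2)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = fitted, colour = "firebrick") +
    ggplot2::labs(x = "lag (min)", y = expression(MSD ~ (mu * m^2)),
                  subtitle = sprintf("D = %.3g µm²/min, P = %.3g min",
                                     object$D, object$P)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hill_fit <- function(object, ...) {
  means <- object$means
  pos <- means$dose[means$dose > 0]
  grid <- tibble::tibble(dose = exp(seq(log(min(pos)), log(max(pos)),
                                        length.out = 200L)))
  grid$mean_response <- hill_response(grid$dose, object$bottom, object$top,
                                      object$ec50, object$hill_coef)
  ggplot2::ggplot(means, ggplot2::aes(.data$dose, .data$mean_response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (nM)", y = "peak response (Δ ratio)",
                  subtitle = sprintf("EC50 = %.3g nM, Hill = %.2g",
                                     object$ec50, object$hill_coef)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.coupling_summary <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(.data$bin_mid, .data$mean_speed_um_min)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "G/R ratio (bin center)",
                  y = "mean speed (µm/min)") +
    ggplot2::theme_minimal()
}

#' Plot single-cell ratio traces
#'
#' @param trace A tibble `cell_id`, `time_s`, `ratio`.
#' @param stim_time Optional stimulus time drawn as a vertical line.
#' @return A ggplot.
#' @export
plot_ratio_traces <- function(trace, stim_time = NULL) {
  p <- ggplot2::ggplot(trace, ggplot2::aes(.data$time_s / 60, .data$ratio,
                                           group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "time (min)", y = "G/R ratio") +
    ggplot2::theme_minimal()
  if (!is.null(stim_time)) {
    p <- p + ggplot2::geom_vline(xintercept = stim_time / 60, linetype = 2,
                                 colour = "grey50")
  }
  p
}
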