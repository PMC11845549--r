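#' Plot a classified event timeline
#'
#' Events as coloured spans over time, one band, in the style of the usual
#' classification overview figures.
#'
#' @param object an event sequence.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.event_seq <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(xmin = .data$t_on, xmax = .data$t_off,
                 ymin = 0, ymax = 1, fill = .data$kind)) +
    geom_rect() +
    scale_y_continuous(breaks = NULL) +
    labs(x = "time (s)", y = NULL, fill = "event") +
    theme_minimal()
}

#' Plot a velocity series with classification threshold
#'
#' @param vs a (conditioned, optionally labeled) velocity series.
#' @param log_y log-scale the velocity axis.
#' @return A ggplot.
#' @export
plot_velocity <- function(vs, log_y = TRUE) {
  p <- ggplot(vs, aes(.data$t, .data$w_eye)) +
    geom_line(na.rm = TRUE, colour = "darkgreen") +
    labs(x = "time (s)", y = "eye angular velocity (deg/s)") +
    theme_minimal()
  if ("threshold" %in% names(vs)) {
    p <- p + geom_step(aes(y = .data$threshold), colour = "grey40",
                       linetype = "dashed", na.rm = TRUE)
  }
  if (log_y) p <- p + scale_y_log10()
  p
}

#' Main-sequence scatter plot
#'
#' @param seq an event sequence with saccade amplitudes.
#' @return A ggplot of peak velocity against amplitude for saccades.
#' @export
plot_main_sequence <- function(seq) {
  df <- as_tibble(seq) |>
    dplyr::filter(.data$kind == "saccade", !is.na(.data$amplitude_deg))
  ggplot(df, aes(.data$amplitude_deg, .data$peak_vel_dps)) +
    geom_point(alpha = 0.4) +
    labs(x = "saccade amplitude (deg)", y = "peak velocity (deg/s)") +
    theme_minimal()
}

#' Plot a time-frequency map
#'
#' @param object a trial-averaged `tf_map` (µV² or dB).
#' @param ... unused.
#' @return A ggplot raster of power over time and frequency.
#' @exportS3Method ggplot2::autoplot
autoplot.tf_map <- function(object, ...) {
  if (length(dim(object$power)) == 3) object <- tf_average(object)
  df <- tidyr::expand_grid(freq = object$freqs, time = object$times)
  df$power <- as.vector(t(object$power))
  ggplot(df, aes(.data$time, .data$freq, fill = .data$power)) +
    geom_raster() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    labs(x = "time from gaze onset (s)", y = "frequency (Hz)",
         fill = attr(object, "units") %||% "power") +
    theme_minimal()
}

#' Plot a fixation-onset ERP
#'
#' @param erp a channels x time matrix from [average_erp()].
#' @param channels channels to draw (default all).
#' @return A ggplot of the ERP time courses.
#' @export
plot_erp <- function(erp, channels = rownames(erp)) {
  times <- attr(erp, "times")
  df <- tibble(channel = rep(channels, each = length(times)),
               t = rep(times, length(channels)),
               uv = as.vector(t(erp[channels, , drop = FALSE])))
  ggplot(df, aes(.data$t, .data$uv, colour = .data$channel)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dotted") +
    labs(x = "time from gaze onset (s)", y = "amplitude (µV)") +
    theme_minimal()
}
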