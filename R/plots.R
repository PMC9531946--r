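#' Plot methods
#'
#' `autoplot()` methods produce the standard figures of a PAPA-SPT
#' analysis: sawtooth intensity traces with pulse markers, diffusion
#' spectra on a log D axis, per-pulse responses, and decay histograms.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name papaspt-plots
NULL

#' @rdname papaspt-plots
#' @export
autoplot.papa_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$frame,
                                            y = .data$intensity)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "frame", y = "total intensity (photons)")
  proto <- attr(object, "protocol")
  if (!is.null(proto)) {
    marks <- bind_rows(
      tibble(frame = pulse_frames(proto, "G"), channel = "green"),
      tibble(frame = pulse_frames(proto, "V"), channel = "violet"))
    if (nrow(marks)) {
      p <- p + ggplot2::geom_vline(
        data = marks,
        ggplot2::aes(xintercept = .data$frame, colour = .data$channel),
        alpha = 0.6, linewidth = 0.3) +
        ggplot2::scale_colour_manual(
          values = c(green = "#2e8b57", violet = "#8a2be2"), name = "pulse")
    }
  }
  p
}

#' @rdname papaspt-plots
#' @export
autoplot.papa_spectrum <- function(object, ...) {
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$d, y = .data$occupation)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(D ~ (mu * m^2 / s)), y = "occupation")
}

#' @rdname papaspt-plots
#' @export
autoplot.papa_pulse_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$channel,
                                       y = .data$increase,
                                       colour = .data$channel)) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4) +
    ggplot2::scale_colour_manual(
      values = c(G = "#2e8b57", V = "#8a2be2"), guide = "none") +
    ggplot2::labs(x = "pulse channel", y = "intensity increase")
}

#' @rdname papaspt-plots
#' @export
autoplot.papa_decay <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns,
                                       y = .data$counts)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "photons")
}

#' Compare PAPA and DR diffusion spectra
#'
#' @param papa_spectrum,dr_spectrum `papa_spectrum` objects on one grid.
#' @return A ggplot overlaying the two spectra.
#' @export
plot_spectra_comparison <- function(papa_spectrum, dr_spectrum) {
  df <- bind_rows(
    mutate(papa_spectrum$spectrum, class = "PAPA"),
    mutate(dr_spectrum$spectrum, class = "DR"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d, y = .data$occupation,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(PAPA = "#2e8b57",
                                            DR = "#8a2be2")) +
    ggplot2::labs(x = expression(D ~ (mu * m^2 / s)), y = "occupation")
}
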