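#' Plot sensorgrams
#'
#' Association/dissociation curves coloured by analyte concentration.
#'
#' @param curves Sensorgram tibble (`time_s`, `response_RU`,
#'   `concentration_M`).
#' @param t_switch Optional buffer-switch time to mark (s).
#' @return A ggplot object.
#' @export
plot_sensorgrams <- function(curves, t_switch = NULL) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(
    x = .data$time_s, y = .data$response_RU,
    colour = factor(signif(.data$concentration_M, 3)),
    group = .data$concentration_M
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  colour = "Analyte (M)") +
    ggplot2::theme_minimal()
  if (!is.null(t_switch)) {
    p <- p + ggplot2::geom_vline(xintercept = t_switch, linetype = "dashed")
  }
  p
}

#' Plot a fitted Langmuir model over the data
#'
#' @param object A `langmuir_fit`.
#' @param ... Unused.
#' @return A ggplot object: observed points (thinned) and fitted curves.
#' @exportS3Method ggplot2::autoplot
autoplot.langmuir_fit <- function(object, ...) {
  d <- object$data
  fitted <- dplyr::mutate(d, response_RU = langmuir_response(
    d$time_s, d$concentration_M, object$kon, object$koff, object$rmax,
    object$t_switch
  ))
  thin <- d[unique(round(seq(1, nrow(d), length.out = min(nrow(d), 600)))), ]
  ggplot2::ggplot(mapping = ggplot2::aes(
    x = .data$time_s, y = .data$response_RU,
    colour = factor(signif(.data$concentration_M, 3)),
    group = .data$concentration_M
  )) +
    ggplot2::geom_point(data = thin, size = 0.4, alpha = 0.5) +
    ggplot2::geom_line(data = fitted) +
    ggplot2::labs(x = "Time (s)", y = "Response (RU)",
                  colour = "Analyte (M)",
                  title = sprintf("1:1 Langmuir fit: KD = %.3g M", object$kd)) +
    ggplot2::theme_minimal()
}

#' Plot a hinge-angle series
#'
#' @param series Tibble from [hinge_angle_series()].
#' @return A ggplot object.
#' @export
plot_angle_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame, y = .data$angle_deg)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Frame", y = "Hinge angle (degrees)") +
    ggplot2::theme_minimal()
}

#' Plot per-chain glycan state occupancy
#'
#' @param states Classification tibble from [classify_glycan_states()].
#' @return A ggplot stacked-bar chart of bound/loose fractions per chain.
#' @export
plot_state_fractions <- function(states) {
  state_fractions(states) |>
    tidyr::pivot_longer(c("f_bound", "f_loose"), names_to = "state",
                        names_prefix = "f_", values_to = "fraction") |>
    ggplot2::ggplot(ggplot2::aes(x = .data$chain, y = .data$fraction,
                                 fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Glycan chain", y = "Fraction of frames",
                  fill = "Configuration") +
    ggplot2::theme_minimal()
}
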