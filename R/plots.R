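#' Plot a windowed flux table
#'
#' Per-dwell net CO2 flux against time, one colour per chamber.
#'
#' @param fluxes Output of [windowed_chamber_fluxes()].
#' @return A ggplot object.
#' @export
plot_fluxes <- function(fluxes) {
  fluxes |>
    dplyr::mutate(t_mid = (.data$window_start_s + .data$window_end_s) / 2 / 3600) |>
    ggplot2::ggplot(ggplot2::aes(.data$t_mid, .data$A,
                                 colour = factor(.data$chamber_id))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (h)",
                  y = expression(A~(mu*mol~CO[2]~m^-2~s^-1)),
                  colour = "chamber") +
    ggplot2::theme_minimal()
}

#' Plot a PPFD profile
#'
#' @param profile A tibble with `time_s` and `ppfd`.
#' @return A ggplot object.
#' @export
plot_light_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$time_s / 3600, .data$ppfd)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::labs(x = "local solar time (h)",
                  y = expression(PPFD~(mu*mol~m^-2~s^-1))) +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity sweep
#'
#' Percentage error of the inverted source term against the normalized
#' parameter change, one panel line per variable.
#'
#' @param sweep Output of [sensitivity_sweep()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sweep) {
  ggplot2::ggplot(sweep, ggplot2::aes(.data$normalized_change,
                                      .data$percent_error,
                                      colour = .data$term,
                                      group = interaction(.data$term,
                                                          .data$chamber_F))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "normalized parameter change (%)",
                  y = "error (% of nominal Sx)", colour = "variable") +
    ggplot2::theme_minimal()
}

#' Plot a fitted chamber transient
#'
#' Measured Delta-CO2 with the fitted transient and its steady-state
#' asymptote overlaid.
#'
#' @param object A `transient_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot transient_fit
#' @export
autoplot.transient_fit <- function(object, ...) {
  ss <- object$params[["Sx"]] / object$F_mol
  ggplot2::ggplot(object$data, ggplot2::aes(.data$time, .data$delta_co2)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::geom_hline(yintercept = ss, linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = expression(Delta*CO[2]~(ppm))) +
    ggplot2::theme_minimal()
}
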