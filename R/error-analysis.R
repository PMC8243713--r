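#' Sensitivity ranges for the error analysis
#'
#' The measured-variable ranges swept in the root-sum-square error analysis
#' of the source-term inversion. Defaults are the system's operating ranges:
#' air flux 0.2-0.6 mol/s, initial source term 0-5 micromol/s, dead time
#' 0-100 s, Delta-CO2 0-10 ppm.
#'
#' @param F_range,S0_range,t0_range,delta_co2_range Two-element ordered
#'   numeric ranges.
#' @return A list of class `sensitivity_ranges`.
#' @export
sensitivity_ranges <- function(F_range = c(0.2, 0.6), S0_range = c(0, 5),
                               t0_range = c(0, 100),
                               delta_co2_range = c(0, 10)) {
  rngs <- list(F = F_range, S0 = S0_range, t0 = t0_range,
               delta_co2 = delta_co2_range)
  if (!all(purrr::map_lgl(rngs, ~ length(.x) == 2 && .x[[2]] >= .x[[1]]))) {
    abort("each range must be an ordered pair", class = "canopyflux_domain_error")
  }
  structure(rngs, class = "sensitivity_ranges")
}

#' Partial derivatives of the inverted source term
#'
#' Analytic partial derivatives of the source-term inversion
#' \eqn{S_x = (\Delta CO_2 F - S_0 e^{-x})/(1 - e^{-x})},
#' \eqn{x = \frac{F}{V}\tau(t - t_0)}, with respect to the measured variables
#' F, S0, Delta-CO2 and t0.
#'
#' @param params A [transient_params()] object (`Sx` ignored).
#' @param delta_co2 The measured Delta-CO2 at which to evaluate, ppm.
#' @param t Evaluation time, s; must exceed `t0`.
#' @return A tibble with one row and columns `dSx_dF`, `dSx_dS0`,
#'   `dSx_ddelta_co2`, `dSx_dt0`.
#' @export
partial_derivatives <- function(params, delta_co2, t) {
  stopifnot(inherits(params, "transient_params"))
  if (t <= params$t0) {
    abort("partials are singular at t <= t0", class = "canopyflux_singular_error")
  }
  with(params, {
    k <- (F_mol / V) * tau
    x <- k * (t - t0)
    e <- exp(-x)
    D <- 1 - e
    Sx_val <- (delta_co2 * F_mol - S0 * e) / D
    tibble::tibble(
      dSx_dF = (delta_co2 + S0 * e * x / F_mol) / D -
        Sx_val * e * x / (F_mol * D),
      dSx_dS0 = -e / D,
      dSx_ddelta_co2 = F_mol / D,
      dSx_dt0 = k * e * (Sx_val - S0) / D
    )
  })
}

#' Root-sum-square error of the inverted source term
#'
#' Error contribution of each measured variable (its partial derivative times
#' the magnitude of its parameter range) and their root-sum-square total:
#' \deqn{T = \sqrt{\sum_v \left(\frac{\partial S_x}{\partial v}\,\bar v\right)^2}}
#' assuming independent errors.
#'
#' @param params A [transient_params()] object.
#' @param ranges A [sensitivity_ranges()]; each variable's weight is its
#'   range width (upper minus lower).
#' @param delta_co2 Delta-CO2 at the evaluation point, ppm; defaults to the
#'   closed-form value at `t` for the nominal `params$Sx`.
#' @param t Evaluation time, s; defaults to steady state
#'   (`t0 + 10 V / F`).
#' @return A tibble with the four components (micromol/s), the total `T`, and
#'   each as percent of the nominal `params$Sx` (`NA` if that is zero).
#' @export
total_error <- function(params, ranges = sensitivity_ranges(),
                        delta_co2 = NULL, t = NULL) {
  stopifnot(inherits(params, "transient_params"),
            inherits(ranges, "sensitivity_ranges"))
  t <- t %||% (params$t0 + 10 * params$V / params$F_mol)
  delta_co2 <- delta_co2 %||% delta_co2_closed_form(params, t)
  pd <- partial_derivatives(params, delta_co2, t)
  w <- purrr::map_dbl(ranges, ~ diff(.x))
  comp <- c(F = pd$dSx_dF * w[["F"]],
            S0 = pd$dSx_dS0 * w[["S0"]],
            delta_co2 = pd$dSx_ddelta_co2 * w[["delta_co2"]],
            t0 = pd$dSx_dt0 * w[["t0"]])
  total <- sqrt(sum(comp^2))
  pct <- if (params$Sx != 0) abs(c(comp, total)) / abs(params$Sx) * 100
         else rep(NA_real_, 5)
  tibble::tibble(
    term = c(names(comp), "total"),
    error_umol_s = unname(c(comp, total)),
    percent_of_Sx = unname(pct)
  )
}

#' Sensitivity sweep over normalized parameter changes
#'
#' For each measured variable, evaluates its error contribution to the
#' inverted source term over a grid of parameter changes from 0 to the full
#' range width (expressed as a normalized 0-100 % change), as a percentage of
#' the nominal source term. Supplying several `F_mol` values (one per
#' chamber) yields one sweep per chamber for aggregation.
#'
#' @param ranges A [sensitivity_ranges()].
#' @param grid_points Number of grid positions (>= 2).
#' @param nominal_Sx Nominal source term, micromol/s; must be nonzero.
#' @param F_mol One or more air-flux values (e.g. the 12 chamber flows).
#' @param V Chamber content, mol.
#' @param t Evaluation time; default steady state (`t0 + 10 V / F`).
#' @param t0,tau Delay parameters of the evaluation point.
#' @return A tibble with `chamber_F`, `term`, `normalized_change` (0-100),
#'   `percent_error`.
#' @export
sensitivity_sweep <- function(ranges = sensitivity_ranges(), grid_points = 21,
                              nominal_Sx = 3, F_mol = 0.34, V = 19.3,
                              t = NULL, t0 = 0, tau = 1) {
  if (grid_points < 2) abort("grid_points must be >= 2",
                             class = "canopyflux_domain_error")
  if (nominal_Sx == 0) abort("percentage errors undefined for nominal Sx = 0",
                             class = "canopyflux_domain_error")
  grid <- seq(0, 1, length.out = grid_points)
  purrr::map_dfr(F_mol, function(f) {
    params <- transient_params(F_mol = f, V = V, S0 = 0, Sx = nominal_Sx,
                               t0 = t0, tau = tau)
    t_eval <- t %||% (t0 + 10 * V / f)
    dco2 <- delta_co2_closed_form(params, t_eval)
    pd <- partial_derivatives(params, dco2, t_eval)
    deriv <- c(F = pd$dSx_dF, S0 = pd$dSx_dS0,
               delta_co2 = pd$dSx_ddelta_co2, t0 = pd$dSx_dt0)
    widths <- purrr::map_dbl(ranges, ~ diff(.x))
    tidyr::expand_grid(term = names(deriv), g = grid) |>
      dplyr::mutate(
        chamber_F = f,
        normalized_change = .data$g * 100,
        percent_error = unname(abs(unlist(deriv)[.data$term] *
                                     widths[.data$term] * .data$g)) /
          abs(nominal_Sx) * 100
      ) |>
      dplyr::select("chamber_F", "term", "normalized_change", "percent_error")
  })
}
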