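#' Chamber mass-balance rate of change
#'
#' Rate of change of the chamber CO2 mole fraction for a well-mixed open
#' chamber: air enters from the buffer at molar flux `F_mol` carrying `co2_in`,
#' the canopy removes `Sx` (positive = removal), and chamber air leaves at the
#' chamber concentration:
#'
#' \deqn{dC/dt = (F \cdot C_{in} - S_x)/V - F \cdot C/V}
#'
#' @param co2_chamber Chamber CO2, micromol/mol (ppm).
#' @param co2_in Inlet (buffer) CO2, ppm.
#' @param F_mol Molar air flux through the chamber, mol/s.
#' @param Sx Source term, micromol CO2/s (positive = removal by the canopy).
#' @param V Chamber air content, mol.
#' @return dCO2/dt in ppm/s.
#' @examples
#' dco2_dt(400, 400, F_mol = 0.34, Sx = 3, V = 19.3) # -3/19.3
#' @export
dco2_dt <- function(co2_chamber, co2_in, F_mol, Sx, V) {
  if (any(V <= 0)) abort("V must be positive", class = "canopyflux_domain_error")
  (F_mol * co2_in - Sx) / V - F_mol * co2_chamber / V
}

#' Transient-model parameter set
#'
#' Bundles the parameters of the chamber transient: molar air flux `F_mol`
#' (mol/s), chamber content `V` (mol), source term at time zero `S0` and
#' current source term `Sx` (micromol CO2/s, positive = removal), dead time
#' `t0` (s) and residence-time multiplier `tau` (unitless; 1 = perfect
#' mixing).
#'
#' @param F_mol Molar air flux, mol/s.
#' @param V Chamber content, mol.
#' @param S0 Source term at time zero, micromol CO2/s.
#' @param Sx Current source term, micromol CO2/s.
#' @param t0 Dead time, s.
#' @param tau Residence-time multiplier, unitless.
#' @return A list of class `transient_params`.
#' @export
transient_params <- function(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3,
                             t0 = 0, tau = 1) {
  if (F_mol <= 0 || V <= 0 || t0 < 0 || tau <= 0) {
    abort("need F_mol > 0, V > 0, t0 >= 0, tau > 0",
          class = "canopyflux_domain_error")
  }
  structure(list(F_mol = F_mol, V = V, S0 = S0, Sx = Sx, t0 = t0, tau = tau),
            class = "transient_params")
}

#' Closed-form chamber transient
#'
#' The exponential solution of the chamber mass balance for a step in the
#' source term, extended with the residence-time multiplier `tau`:
#'
#' \deqn{\Delta CO_2(t) = \frac{1}{F}\left(S_x + (S_0 - S_x)
#'   e^{-\frac{F}{V}\tau (t - t_0)}\right)}
#'
#' where \eqn{\Delta CO_2 = CO_{2,in} - CO_{2,chamber}} (positive while the
#' canopy or scrubber removes CO2). For `t < t0` the pre-step value `S0/F` is
#' returned.
#'
#' @param params A [transient_params()] object.
#' @param t Time(s), s; may be a vector.
#' @return Delta-CO2 in ppm at each `t`.
#' @examples
#' p <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3)
#' delta_co2_closed_form(p, p$V / p$F_mol) # 3*(1-exp(-1))/0.34
#' @export
delta_co2_closed_form <- function(params, t) {
  stopifnot(inherits(params, "transient_params"))
  with(params, {
    expo <- exp(-(F_mol / V) * tau * pmax(t - t0, 0))
    (Sx + (S0 - Sx) * expo) / F_mol
  })
}

#' Numerically integrate the chamber mass balance
#'
#' Adaptive-step integration of the chamber ODE under arbitrary time-varying
#' inlet concentration and source term. For constant forcing the solution
#' matches [delta_co2_closed_form()] (with `tau = 1`) to the solver tolerance.
#'
#' @param params A [transient_params()] object (`F_mol`, `V` used).
#' @param co2_in Inlet CO2: a constant or a function of time returning ppm.
#' @param Sx Source term: a constant or a function of time, micromol CO2/s.
#' @param times Strictly increasing output times, s.
#' @param co2_init Initial chamber CO2, ppm.
#' @param rtol,atol Solver tolerances.
#' @return A tibble with columns `time` and `co2_chamber`.
#' @export
integrate_chamber <- function(params, co2_in, Sx, times, co2_init,
                              rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(params, "transient_params"))
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", class = "canopyflux_domain_error")
  }
  cin_f <- if (is.function(co2_in)) co2_in else function(t) co2_in
  sx_f <- if (is.function(Sx)) Sx else function(t) Sx
  deriv <- function(t, y, parms) {
    list(dco2_dt(y[[1]], cin_f(t), params$F_mol, sx_f(t), params$V))
  }
  sol <- deSolve::lsoda(y = c(co2 = co2_init), times = times, func = deriv,
                        parms = NULL, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[[1]] < 0) {
    abort("ODE solver failed to integrate the chamber model",
          class = "canopyflux_solver_error")
  }
  tibble::tibble(time = sol[, "time"], co2_chamber = sol[, "co2"])
}

#' Invert the chamber transient for the source term
#'
#' Solves the closed-form transient for the source term `Sx` given a measured
#' Delta-CO2 at time `t`:
#'
#' \deqn{S_x = \frac{\Delta CO_2 \cdot F}{1 - e^{-\frac{F}{V}\tau(t-t_0)}}
#'   - \frac{S_0 e^{-\frac{F}{V}\tau(t-t_0)}}{1 - e^{-\frac{F}{V}\tau(t-t_0)}}}
#'
#' @param delta_co2 Measured inlet-minus-chamber CO2, ppm.
#' @param params A [transient_params()] object; its `Sx` entry is ignored.
#' @param t Time(s) of the measurement, s; must exceed `t0`.
#' @return Source term Sx in micromol CO2/s.
#' @export
invert_for_sx <- function(delta_co2, params, t) {
  stopifnot(inherits(params, "transient_params"))
  if (any(t <= params$t0)) {
    abort("inversion is singular at t <= t0", class = "canopyflux_singular_error")
  }
  with(params, {
    expo <- exp(-(F_mol / V) * tau * (t - t0))
    (delta_co2 * F_mol - S0 * expo) / (1 - expo)
  })
}

#' Steady-state Delta-CO2
#'
#' The asymptote of the chamber transient: `Sx / F`.
#'
#' @param Sx Source term, micromol CO2/s.
#' @param F_mol Molar air flux, mol/s.
#' @return Steady-state Delta-CO2 in ppm.
#' @export
steady_state_delta <- function(Sx, F_mol) {
  if (any(F_mol <= 0)) abort("F_mol must be positive",
                             class = "canopyflux_domain_error")
  Sx / F_mol
}

#' Settling time of the chamber transient
#'
#' Time after the dead time at which the transient first comes within a
#' fraction `eps` of its full steady-state step:
#' \eqn{t - t_0 = \frac{V}{F \tau} \ln(1/\epsilon)}.
#'
#' @param params A [transient_params()] object.
#' @param eps Remaining fraction of the step, e.g. 0.005 for 0.5%.
#' @return Settling time in seconds (measured from `t0`).
#' @examples
#' settling_time(transient_params(F_mol = 0.34, V = 19.3)) # about 300 s
#' @export
settling_time <- function(params, eps = 0.005) {
  stopifnot(inherits(params, "transient_params"))
  if (eps <= 0 || eps >= 1) abort("eps must be in (0, 1)",
                                  class = "canopyflux_domain_error")
  with(params, (V / (F_mol * tau)) * log(1 / eps))
}
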