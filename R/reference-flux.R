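#' Simulated photosynthesis from a CO2-scrub event
#'
#' A soda-lime scrubber pumping chamber air at `scrub_flux` litres per second
#' creates a known artificial CO2 uptake. Two conventions are provided:
#'
#' * `physical` (default): the scrubber removes the CO2 carried by its pumped
#'   air stream, so with molar pump flow
#'   \eqn{n = scrub\_flux \cdot 10^{-3} P / (R (T + 273.15))} the reference
#'   flux is \eqn{A_{sim} = -n \cdot CO_{2,chamber} / S} (micromol m^-2 s^-1,
#'   negative = uptake).
#' * `as_printed`: \eqn{A_{sim} = -1000 \cdot n}, the historical formulation
#'   that omits the chamber CO2 concentration and area.
#'
#' @param scrub_flux Scrub pump speed, l/s.
#' @param pressure Air pressure, Pa.
#' @param temp Air temperature, degrees C.
#' @param co2_chamber Chamber CO2, ppm (required in physical mode).
#' @param area_S Chamber floor area, m^2.
#' @param mode `"physical"` or `"as_printed"`.
#' @return A_sim in micromol CO2 m^-2 s^-1 (negative).
#' @examples
#' simulated_photosynthesis(0.2, 101300, 25, co2_chamber = 410) # ~ -9.31
#' @export
simulated_photosynthesis <- function(scrub_flux, pressure = 101300, temp = 25,
                                     co2_chamber = NULL, area_S = 0.36,
                                     mode = c("physical", "as_printed")) {
  mode <- match.arg(mode)
  if (any(scrub_flux < 0)) abort("scrub_flux must be non-negative",
                                 class = "canopyflux_domain_error")
  k <- phys_constants()
  n_mol <- scrub_flux * 1e-3 * pressure / (k$R * (temp + k$zero_celsius))
  if (mode == "physical") {
    if (is.null(co2_chamber)) {
      abort("physical mode needs the chamber CO2 concentration",
            class = "canopyflux_missing_parameter_error")
    }
    -n_mol * co2_chamber / area_S
  } else {
    -1000 * n_mol
  }
}

#' Simulated respiration from a CO2-injection event
#'
#' Pure CO2 injected at `co2_injected` ml/s creates a known artificial
#' release: \eqn{R_{sim} = CO_{2,injected} P / (S (T + 273.15) R)}.
#' The unit conversions cancel exactly (ml to m^3 is 1e-6, mol to micromol is
#' 1e6), so the expression is evaluated as written.
#'
#' @param co2_injected Injected CO2 flux, ml/s.
#' @param pressure Air pressure, Pa.
#' @param temp Chamber temperature, degrees C.
#' @param area_S Chamber floor area, m^2.
#' @return R_sim in micromol CO2 m^-2 s^-1 (positive).
#' @examples
#' simulated_respiration(0.1, 101300, 25) # ~ +11.35
#' @export
simulated_respiration <- function(co2_injected, pressure = 101300, temp = 25,
                                  area_S = 0.36) {
  if (any(co2_injected < 0)) abort("co2_injected must be non-negative",
                                   class = "canopyflux_domain_error")
  k <- phys_constants()
  co2_injected * pressure / (area_S * (temp + k$zero_celsius) * k$R)
}

#' Build a step-ramp forcing schedule
#'
#' The calibration protocol holds the reference pump at each level for
#' `step_duration_s` seconds, ascending through all levels and then
#' descending from the highest back to the lowest (the peak level is visited
#' in both passes).
#'
#' @param levels Ordered increasing positive pump speeds (l/s or ml/s).
#' @param step_duration_s Seconds per step (default 600).
#' @param extraction_window_s Final seconds of each step used for flux
#'   extraction (default 60); must be shorter than the step.
#' @return A tibble with `step`, `start_s`, `end_s`, `level`, of class
#'   `ramp_schedule` (attributes `step_duration_s`, `extraction_window_s`).
#' @export
build_ramp_schedule <- function(levels, step_duration_s = 600,
                                extraction_window_s = 60) {
  if (any(levels <= 0) || is.unsorted(levels, strictly = TRUE)) {
    abort("levels must be positive and strictly increasing",
          class = "canopyflux_domain_error")
  }
  if (step_duration_s <= extraction_window_s) {
    abort("step_duration_s must exceed extraction_window_s",
          class = "canopyflux_domain_error")
  }
  seq_levels <- c(levels, rev(levels))
  out <- tibble::tibble(
    step = seq_along(seq_levels),
    start_s = (seq_along(seq_levels) - 1) * step_duration_s,
    end_s = seq_along(seq_levels) * step_duration_s,
    level = seq_levels
  )
  structure(out, step_duration_s = step_duration_s,
            extraction_window_s = extraction_window_s,
            class = c("ramp_schedule", class(out)))
}

#' Look up the ramp level at given times
#'
#' @param schedule A `ramp_schedule`.
#' @param times Times in seconds.
#' @return The pump level of the enclosing step at each time (NA outside the
#'   schedule).
#' @export
ramp_level_at <- function(schedule, times) {
  idx <- findInterval(times, schedule$start_s)
  out <- rep(NA_real_, length(times))
  ok <- idx >= 1 & times < max(schedule$end_s)
  out[ok] <- schedule$level[idx[ok]]
  out[times == max(schedule$end_s)] <- schedule$level[[nrow(schedule)]]
  out
}

#' Extract per-step fluxes from a ramp run
#'
#' Means the measured flux over the final `extraction_window_s` seconds of
#' each step of the protocol (by which time the chamber has settled).
#'
#' @param times Measurement times, s.
#' @param flux Measured flux at each time.
#' @param schedule A `ramp_schedule` from [build_ramp_schedule()].
#' @param extraction_window_s Override of the schedule's extraction window.
#' @return A tibble with `step`, `level`, `mean_flux`, `n_samples`. Steps
#'   with no samples in the window are skipped with a warning.
#' @export
extract_step_fluxes <- function(times, flux, schedule,
                                extraction_window_s = NULL) {
  w <- extraction_window_s %||% attr(schedule, "extraction_window_s")
  if (w >= attr(schedule, "step_duration_s")) {
    abort("extraction window must be shorter than the step",
          class = "canopyflux_domain_error")
  }
  out <- purrr::pmap_dfr(schedule, function(step, start_s, end_s, level) {
    keep <- times >= end_s - w & times <= end_s
    tibble::tibble(step = step, level = level,
                   mean_flux = mean(flux[keep]), n_samples = sum(keep))
  })
  skipped <- out$n_samples == 0
  if (any(skipped)) {
    warn(paste0(sum(skipped), " step(s) had no samples in the extraction window"))
    out <- out[!skipped, , drop = FALSE]
  }
  out
}

#' Normalize ramp transients to a common shape
#'
#' Scales a Delta-CO2 transient by `Sx / (S0 - Sx)` and then min-max rescales
#' to \[0, 1\], so transients recorded at different pump speeds collapse onto
#' their common exponential shape and settling speed can be compared across
#' air fluxes.
#'
#' @param delta_co2 Delta-CO2 trace, ppm.
#' @param Sx_level Scrubbed flux of this step, micromol/s.
#' @param S0 Flux at time zero, micromol/s; must differ from `Sx_level`.
#' @return Numeric vector in \[0, 1\].
#' @export
normalize_ramps <- function(delta_co2, Sx_level, S0 = 0) {
  if (Sx_level == S0) abort("Sx_level must differ from S0",
                            class = "canopyflux_domain_error")
  scaled <- delta_co2 * Sx_level / (S0 - Sx_level)
  rng <- range(scaled)
  if (rng[[1]] == rng[[2]]) {
    abort("constant series: min-max normalization undefined",
          class = "canopyflux_degenerate_error")
  }
  (scaled - rng[[1]]) / (rng[[2]] - rng[[1]])
}

#' Measured-versus-simulated validation regression
#'
#' Ordinary least-squares regression of measured fluxes on the reference
#' fluxes simulated by scrubbing/injection, the system's accuracy check. A
#' well-calibrated system gives slope 1, intercept 0.
#'
#' @param measured,simulated Paired flux values (n >= 3).
#' @return A tibble with `slope`, `intercept`, `r.squared`, `p.value` (two-
#'   sided t-test on the slope), `n`.
#' @export
validation_regression <- function(measured, simulated) {
  if (length(measured) != length(simulated) || length(measured) < 3) {
    abort("need >= 3 paired values", class = "canopyflux_domain_error")
  }
  fit <- lm(measured ~ simulated)
  s <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[["simulated"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r.squared = s$r.squared,
    p.value = s$coefficients["simulated", "Pr(>|t|)"],
    n = length(measured)
  )
}
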