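#' Light regime configuration
#'
#' Parameters generating the daily PPFD forcing: site latitude/longitude,
#' day of year, maximum PPFD at solar noon, and the fluctuation design
#' (fractional amplitude, period, waveform). Defaults describe a mid-latitude
#' summer-solstice day (46.07 N, 13.23 E, day 172) peaking at 1000
#' micromol m^-2 s^-1, fluctuated +/-50 % with a 120-s period.
#'
#' @param latitude Degrees north.
#' @param longitude Degrees east (kept for provenance; local solar time is
#'   used directly).
#' @param day_of_year 1-366.
#' @param ppfd_max PPFD at solar noon, micromol m^-2 s^-1.
#' @param fluct_fraction Fractional fluctuation amplitude in \[0, 1).
#' @param fluct_period_s Fluctuation period, s.
#' @param waveform `"square"` (default) or `"sine"`.
#' @return A list of class `light_config`.
#' @export
light_config <- function(latitude = 46.07, longitude = 13.23,
                         day_of_year = 172, ppfd_max = 1000,
                         fluct_fraction = 0.5, fluct_period_s = 120,
                         waveform = c("square", "sine")) {
  waveform <- match.arg(waveform)
  if (abs(latitude) > 90 || day_of_year < 1 || day_of_year > 366 ||
      ppfd_max < 0 || fluct_fraction < 0 || fluct_fraction >= 1 ||
      fluct_period_s <= 0) {
    abort("invalid light configuration", class = "canopyflux_domain_error")
  }
  structure(list(latitude = latitude, longitude = longitude,
                 day_of_year = day_of_year, ppfd_max = ppfd_max,
                 fluct_fraction = fluct_fraction,
                 fluct_period_s = fluct_period_s, waveform = waveform),
            class = "light_config")
}

#' Solar elevation angle
#'
#' Standard solar geometry: declination
#' \eqn{\delta = 23.44 \sin(2\pi(284 + N)/365)} from the day of year, hour
#' angle from local solar time, and
#' \eqn{\sin(elev) = \sin\phi \sin\delta + \cos\phi \cos\delta \cos H}.
#' No equation-of-time or timezone correction is applied: the generator needs
#' the profile shape, not astronomical precision.
#'
#' @param config A [light_config()].
#' @param time_s Local solar time in seconds since midnight (vectorised).
#' @return Elevation in degrees.
#' @export
solar_elevation <- function(config, time_s) {
  stopifnot(inherits(config, "light_config"))
  rad <- pi / 180
  decl <- 23.44 * sin(2 * pi * (284 + config$day_of_year) / 365)
  hour_angle <- (time_s / 3600 - 12) * 15
  s <- sin(config$latitude * rad) * sin(decl * rad) +
    cos(config$latitude * rad) * cos(decl * rad) * cos(hour_angle * rad)
  asin(pmin(pmax(s, -1), 1)) / rad
}

#' Daily solar PPFD profile
#'
#' PPFD proportional to the sine of solar elevation, scaled so the solar-noon
#' value equals `ppfd_max` exactly, and zero while the sun is below the
#' horizon.
#'
#' @param config A [light_config()].
#' @param times Local solar times in seconds since midnight.
#' @return A tibble with `time_s` and `ppfd`.
#' @export
daily_ppfd_profile <- function(config, times) {
  stopifnot(inherits(config, "light_config"))
  noon_sin <- sin(solar_elevation(config, 12 * 3600) * pi / 180)
  if (noon_sin <= 0) {
    warn("sun never rises for this configuration; returning all-zero profile")
    return(tibble::tibble(time_s = times, ppfd = 0))
  }
  elev_sin <- sin(solar_elevation(config, times) * pi / 180)
  tibble::tibble(time_s = times,
                 ppfd = config$ppfd_max * pmax(0, elev_sin) / noon_sin)
}

#' Hourly-stepped PPFD profile
#'
#' The facility's light controller updates the commanded PPFD once per clock
#' hour: the solar profile evaluated at each hour start is held for that
#' hour. This is the non-fluctuating treatment, and the base around which the
#' fluctuating treatment oscillates.
#'
#' @param config A [light_config()].
#' @param times Local solar times in seconds since midnight.
#' @return A tibble with `time_s` and `ppfd`.
#' @export
hourly_ppfd_profile <- function(config, times) {
  hour_start <- floor(times / 3600) * 3600
  prof <- daily_ppfd_profile(config, hour_start)
  tibble::tibble(time_s = times, ppfd = prof$ppfd)
}

#' Fluctuating PPFD profile
#'
#' Oscillates a base profile by `+/- fluct_fraction` with the configured
#' period: a square wave alternates `base * (1 + f)` and `base * (1 - f)` for
#' half a period each (a sine modulation is available), so the mean over
#' every full period equals the base exactly and the daily light dose is
#' preserved.
#'
#' @param base A tibble with `time_s` and `ppfd` (e.g. from
#'   [hourly_ppfd_profile()]).
#' @param fluct_fraction Fractional amplitude in \[0, 1).
#' @param fluct_period_s Period, s.
#' @param waveform `"square"` or `"sine"`.
#' @return A tibble with `time_s` and `ppfd`.
#' @export
fluctuating_profile <- function(base, fluct_fraction = 0.5,
                                fluct_period_s = 120,
                                waveform = c("square", "sine")) {
  waveform <- match.arg(waveform)
  if (any(base$ppfd < 0)) abort("base profile must be non-negative",
                                class = "canopyflux_domain_error")
  phase <- (base$time_s %% fluct_period_s) / fluct_period_s
  mod <- if (waveform == "square") {
    ifelse(phase < 0.5, 1 + fluct_fraction, 1 - fluct_fraction)
  } else {
    1 + fluct_fraction * sin(2 * pi * phase)
  }
  tibble::tibble(time_s = base$time_s, ppfd = base$ppfd * mod)
}

#' Daily light integral
#'
#' Trapezoidal integral of a PPFD series converted to mol photons m^-2.
#'
#' @param times Times, s (strictly increasing).
#' @param ppfd PPFD, micromol m^-2 s^-1.
#' @return Light dose in mol photons m^-2.
#' @examples
#' light_integral(c(0, 3600), c(1000, 1000)) # 3.6 mol/m2
#' @export
light_integral <- function(times, ppfd) {
  if (any(diff(times) <= 0)) abort("times must be strictly increasing",
                                   class = "canopyflux_domain_error")
  sum(diff(times) * (head(ppfd, -1) + tail(ppfd, -1)) / 2) * 1e-6
}
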