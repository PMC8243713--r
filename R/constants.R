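#' Physical constants used throughout the package
#'
#' Returns the fixed physical constants of the flux calculations: the universal
#' gas constant in m^3 Pa K^-1 mol^-1, the Celsius-to-Kelvin offset, and the
#' molar mass of carbon in g mol^-1.
#'
#' @return A named list with elements `R`, `zero_celsius`, `molar_mass_C`.
#' @examples
#' phys_constants()$R
#' @export
phys_constants <- function() {
  list(
    R = 8.3144598,        # m^3 Pa K^-1 mol^-1
    zero_celsius = 273.15, # K
    molar_mass_C = 12.011  # g mol^-1
  )
}

#' Chamber geometry
#'
#' Geometry of one growth chamber: floor area `area_S` (m^2), inlet tube
#' cross-section `tube_area` (m^2) and air content `content_V` (mol).
#' Defaults describe a 0.6 x 0.6 m chamber with a 0.10 x 0.10 m inlet duct
#' holding 19.3 mol of air.
#'
#' @param area_S Chamber floor area in m^2.
#' @param tube_area Inlet tube cross-section in m^2.
#' @param content_V Chamber air content in mol.
#' @return A list of class `chamber_geometry`.
#' @examples
#' chamber_geometry()
#' @export
chamber_geometry <- function(area_S = 0.36, tube_area = 0.10 * 0.10,
                             content_V = 19.3) {
  stopifnot(is.numeric(area_S), is.numeric(tube_area), is.numeric(content_V))
  if (area_S <= 0 || tube_area <= 0 || content_V <= 0) {
    abort("chamber geometry values must be strictly positive",
          class = "canopyflux_domain_error")
  }
  structure(list(area_S = area_S, tube_area = tube_area, content_V = content_V),
            class = "chamber_geometry")
}

#' Multiplexer sampling schedule
#'
#' The analyzer dwells on each chamber for `dwell_s` seconds; the first
#' `purge_s` seconds after a valve switch are discarded while the sampling line
#' purges; every `match_interval_s` seconds both analyzer cells are routed the
#' same air (a matching event) to measure the inter-cell offset.
#'
#' @param dwell_s Seconds the analyzer dwells on one chamber.
#' @param purge_s Dead time discarded after a valve switch, seconds.
#' @param match_interval_s Seconds between matching events.
#' @return A list of class `sampling_schedule`.
#' @export
sampling_schedule <- function(dwell_s = 290, purge_s = 110,
                              match_interval_s = 3600) {
  if (!(purge_s >= 0 && purge_s < dwell_s)) {
    abort("need 0 <= purge_s < dwell_s", class = "canopyflux_domain_error")
  }
  if (match_interval_s < dwell_s) {
    abort("match_interval_s must be >= dwell_s",
          class = "canopyflux_domain_error")
  }
  structure(list(dwell_s = dwell_s, purge_s = purge_s,
                 match_interval_s = match_interval_s),
            class = "sampling_schedule")
}

## canonical logger column order; read/write and the simulator all share it
logger_columns <- function() {
  c("timestamp", "chamber_id", "co2_ref", "co2_sample", "h2o_ref",
    "h2o_sample", "flow_velocity", "temp_chamber", "pressure",
    "ppfd_set", "ppfd_transmitted", "mode")
}
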