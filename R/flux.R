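#' Convert flow velocity to molar air flow
#'
#' Converts the miniature flow transmitter's velocity reading (m/s) to a molar
#' air flux through the inlet tube using the ideal gas law:
#' \eqn{air\_flow = flow \cdot S_{tube} \cdot P / (R (T + 273.15))}.
#'
#' @param flow_velocity Air speed in the inlet tube, m/s.
#' @param geometry A [chamber_geometry()] (its `tube_area` is used).
#' @param pressure Air pressure, Pa.
#' @param temp Air temperature, degrees C.
#' @return Molar air flow, mol/s.
#' @examples
#' air_flow_molar(1, chamber_geometry(), 101300, 25) # ~0.409 mol/s
#' @export
air_flow_molar <- function(flow_velocity, geometry = chamber_geometry(),
                           pressure, temp) {
  if (any(pressure <= 0) || any(temp <= -273.15) || any(flow_velocity < 0)) {
    abort("nonphysical input to air_flow_molar",
          class = "canopyflux_domain_error")
  }
  k <- phys_constants()
  flow_velocity * geometry$tube_area * pressure / (k$R * (temp + k$zero_celsius))
}

#' Evapotranspiration flux
#'
#' Water vapour flux per ground area from the inlet/chamber H2O difference,
#' with the dilution denominator:
#' \eqn{E = air\_flow (H_{2}O_{chamber} - H_{2}O_{in}) / (S (1000 - H_{2}O_{chamber}))}.
#'
#' @param air_flow Molar air flow, mol/s.
#' @param h2o_chamber,h2o_in Chamber and inlet H2O, mmol/mol.
#' @param area_S Chamber floor area, m^2.
#' @return E in mol H2O m^-2 s^-1.
#' @export
evapotranspiration <- function(air_flow, h2o_chamber, h2o_in, area_S = 0.36) {
  if (any(h2o_chamber >= 1000)) {
    abort("h2o_chamber must be < 1000 mmol/mol",
          class = "canopyflux_domain_error")
  }
  if (any(area_S <= 0)) abort("area_S must be positive",
                              class = "canopyflux_domain_error")
  air_flow * (h2o_chamber - h2o_in) / (area_S * (1000 - h2o_chamber))
}

#' Net CO2 flux
#'
#' Net canopy CO2 exchange per ground area, with the water-dilution
#' correction:
#' \eqn{A = air\_flow (CO_{2,chamber} - CO_{2,in})/S - CO_{2,chamber} E}.
#' Negative values indicate net uptake (micro-meteorological convention).
#'
#' @param air_flow Molar air flow, mol/s.
#' @param co2_chamber,co2_in Chamber and inlet CO2, micromol/mol.
#' @param area_S Chamber floor area, m^2.
#' @param E Evapotranspiration at the same record, mol m^-2 s^-1.
#' @return A in micromol CO2 m^-2 s^-1.
#' @export
net_co2_flux <- function(air_flow, co2_chamber, co2_in, area_S = 0.36, E = 0) {
  if (any(area_S <= 0)) abort("area_S must be positive",
                              class = "canopyflux_domain_error")
  air_flow * (co2_chamber - co2_in) / area_S - co2_chamber * E
}

## per-record A/E/air_flow columns appended to a logger tibble;
## co2_ref/h2o_ref are the inlet (buffer), co2_sample/h2o_sample the chamber
record_fluxes <- function(records, geometry = chamber_geometry()) {
  records |>
    dplyr::mutate(
      air_flow = air_flow_molar(.data$flow_velocity, geometry,
                                .data$pressure, .data$temp_chamber),
      E = evapotranspiration(.data$air_flow, .data$h2o_sample,
                             .data$h2o_ref, geometry$area_S),
      A = net_co2_flux(.data$air_flow, .data$co2_sample, .data$co2_ref,
                       geometry$area_S, .data$E)
    )
}

#' Compute analyzer matching offsets
#'
#' During a matching event both analyzer cells sample the same air, so any
#' sample-minus-reference difference is inter-cell drift. One offset per event
#' is returned: the mean difference over the event's post-purge records.
#'
#' @param records Logger tibble containing `mode == "match"` rows.
#' @param schedule A [sampling_schedule()]; its `purge_s` defines the records
#'   discarded at the start of each event.
#' @return A tibble with `timestamp_s`, `co2_offset` (ppm), `h2o_offset`
#'   (mmol/mol), `n_samples`; empty (with a warning) if no match events exist.
#' @export
compute_match_offsets <- function(records, schedule = sampling_schedule()) {
  m <- dplyr::filter(records, .data$mode == "match")
  if (nrow(m) == 0) {
    warn("no matching events found; returning empty offset table")
    return(tibble::tibble(timestamp_s = double(), co2_offset = double(),
                          h2o_offset = double(), n_samples = integer()))
  }
  m |>
    dplyr::mutate(event = cumsum(c(TRUE, diff(.data$timestamp) > 30))) |>
    dplyr::group_by(.data$event) |>
    dplyr::filter(.data$timestamp - min(.data$timestamp) >= schedule$purge_s) |>
    dplyr::summarise(
      timestamp_s = mean(.data$timestamp),
      co2_offset = mean(.data$co2_sample - .data$co2_ref),
      h2o_offset = mean(.data$h2o_sample - .data$h2o_ref),
      n_samples = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select(-"event")
}

#' Apply matching correction to logger records
#'
#' Subtracts the inter-cell offset, interpolated to each record's timestamp,
#' from the sample-cell readings. Offsets are interpolated linearly between
#' matching events and held constant before the first and after the last.
#'
#' @param records Logger tibble.
#' @param offsets Offset table from [compute_match_offsets()].
#' @param interpolation `"linear"` (default) or `"constant"` (step-wise,
#'   holding the most recent offset).
#' @return The records with corrected `co2_sample` and `h2o_sample`.
#' @export
apply_match_correction <- function(records, offsets,
                                   interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  if (nrow(offsets) == 0) {
    abort("offset table is empty", class = "canopyflux_domain_error")
  }
  interp <- function(y) {
    if (nrow(offsets) == 1) return(rep(y, nrow(records)))
    approx(offsets$timestamp_s, y, xout = records$timestamp,
           method = interpolation, rule = 2, f = 0)$y
  }
  records |>
    dplyr::mutate(
      co2_sample = .data$co2_sample - interp(offsets$co2_offset),
      h2o_sample = .data$h2o_sample - interp(offsets$h2o_offset)
    )
}

#' Window-averaged per-dwell fluxes
#'
#' Splits the record stream into dwells (runs of a constant chamber id in
#' measure mode), discards each dwell's first `purge_s` seconds while the
#' sampling line purges, computes per-record fluxes, and averages them over
#' the remaining window. Matching rows are ignored. Dwells with no post-purge
#' samples are skipped with a warning.
#'
#' @param records Logger tibble (ideally match-corrected).
#' @param schedule A [sampling_schedule()].
#' @param geometry A [chamber_geometry()].
#' @return A tibble with one row per dwell: `chamber_id`, `window_start_s`,
#'   `window_end_s`, `A`, `E`, `air_flow`, `n_samples`.
#' @export
windowed_chamber_fluxes <- function(records, schedule = sampling_schedule(),
                                    geometry = chamber_geometry()) {
  meas <- records |>
    dplyr::mutate(dwell = cumsum(c(TRUE, diff(.data$chamber_id) != 0))) |>
    dplyr::filter(.data$mode == "measure")
  n_dwells <- dplyr::n_distinct(meas$dwell)
  out <- meas |>
    dplyr::group_by(.data$dwell) |>
    dplyr::mutate(t_rel = .data$timestamp - min(.data$timestamp)) |>
    dplyr::filter(.data$t_rel >= schedule$purge_s,
                  .data$t_rel <= schedule$dwell_s) |>
    dplyr::ungroup()
  if (nrow(out) == 0) {
    warn(paste0(n_dwells,
                " dwell(s) had no samples after the purge window and were skipped"))
    return(tibble::tibble(chamber_id = integer(), window_start_s = double(),
                          window_end_s = double(), A = double(),
                          E = double(), air_flow = double(),
                          n_samples = integer()))
  }
  out <- record_fluxes(out, geometry) |>
    dplyr::group_by(.data$dwell) |>
    dplyr::summarise(
      chamber_id = .data$chamber_id[[1]],
      window_start_s = min(.data$timestamp),
      window_end_s = max(.data$timestamp),
      A = mean(.data$A),
      E = mean(.data$E),
      air_flow = mean(.data$air_flow),
      n_samples = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::select(-"dwell")
  if (nrow(out) < n_dwells) {
    warn(paste0(n_dwells - nrow(out),
                " dwell(s) had no samples after the purge window and were skipped"))
  }
  out
}

#' Cumulative carbon from a flux series
#'
#' Trapezoidal time-integral of the net CO2 flux converted to grams of carbon
#' per ground area. The sign of the flux is preserved: sustained uptake
#' (A < 0) gives a negative cumulative value.
#'
#' @param times Strictly increasing times, s.
#' @param A Net CO2 flux at each time, micromol m^-2 s^-1.
#' @return Cumulative carbon, gC m^-2.
#' @examples
#' cumulative_carbon(c(0, 86400), c(-1, -1)) # ~ -1.038 gC/m2
#' @export
cumulative_carbon <- function(times, A) {
  if (length(times) != length(A)) {
    abort("times and A must have equal length", class = "canopyflux_domain_error")
  }
  if (length(times) < 2) return(0)
  if (any(diff(times) <= 0)) {
    abort("times must be strictly increasing", class = "canopyflux_domain_error")
  }
  umol <- sum(diff(times) * (head(A, -1) + tail(A, -1)) / 2)
  umol * phys_constants()$molar_mass_C * 1e-6
}

#' Per-chamber cumulative carbon from windowed fluxes
#'
#' Each chamber is observed only ~1/12 of the time in a multiplexed system;
#' the integral interpolates A linearly between the window midpoints of
#' successive dwells of the same chamber (trapezoid on the midpoint series).
#'
#' @param fluxes Output of [windowed_chamber_fluxes()].
#' @return A tibble with `chamber_id` and `cum_carbon_gC_m2`.
#' @export
chamber_cumulative_carbon <- function(fluxes) {
  fluxes |>
    dplyr::mutate(t_mid = (.data$window_start_s + .data$window_end_s) / 2) |>
    dplyr::group_by(.data$chamber_id) |>
    dplyr::arrange(.data$t_mid, .by_group = TRUE) |>
    dplyr::summarise(
      cum_carbon_gC_m2 = cumulative_carbon(.data$t_mid, .data$A),
      .groups = "drop"
    )
}

#' Carbon content of harvested biomass
#'
#' Total dry mass (leaves + stems + roots, g m^-2) multiplied by the tissue
#' carbon fraction (default 46.8%), for comparison with the cumulative flux.
#'
#' @param harvest A data frame with columns `dry_mass_leaves`,
#'   `dry_mass_stems`, `dry_mass_roots` (g m^-2), optionally `chamber_id` and
#'   `carbon_fraction`.
#' @param carbon_fraction Default carbon fraction applied where the table has
#'   none.
#' @return The input with a `biomass_carbon_gC_m2` column appended.
#' @export
biomass_carbon <- function(harvest, carbon_fraction = 0.468) {
  if (!all(c("dry_mass_leaves", "dry_mass_stems", "dry_mass_roots") %in%
           names(harvest))) {
    abort("harvest table must have dry_mass_leaves/stems/roots columns",
          class = "canopyflux_schema_error")
  }
  cf <- if ("carbon_fraction" %in% names(harvest)) harvest$carbon_fraction
        else carbon_fraction
  if (any(cf <= 0 | cf >= 1)) {
    abort("carbon_fraction must be in (0, 1)", class = "canopyflux_domain_error")
  }
  if (any(harvest$dry_mass_leaves < 0 | harvest$dry_mass_stems < 0 |
          harvest$dry_mass_roots < 0)) {
    abort("dry masses must be non-negative", class = "canopyflux_domain_error")
  }
  harvest |>
    tibble::as_tibble() |>
    dplyr::mutate(biomass_carbon_gC_m2 = (.data$dry_mass_leaves +
                    .data$dry_mass_stems + .data$dry_mass_roots) * cf)
}
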