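#' Canopy light-response parameters
#'
#' A non-rectangular hyperbola stand-in for a whole-chamber canopy: enough to
#' emulate saturation (midday fluctuations fall in the saturated range) and a
#' linear low-light range, without modelling plant physiology.
#'
#' @param quantum_yield Initial slope, micromol CO2 per micromol photons.
#' @param A_max Gross assimilation capacity per chamber, micromol CO2/s.
#' @param curvature Hyperbola curvature in (0, 1].
#' @param respiration Dark respiration per chamber, micromol CO2/s.
#' @param transp_coef Transpiration per unit gross assimilation,
#'   mol H2O m^-2 s^-1 per (micromol CO2 m^-2 s^-1).
#' @param transp_floor Night-time transpiration floor, mol H2O m^-2 s^-1.
#' @param area_S Ground area the canopy occupies, m^2 (converts PPFD to
#'   photons per chamber).
#' @return A list of class `canopy_params`.
#' @export
canopy_params <- function(quantum_yield = 0.05, A_max = 4, curvature = 0.8,
                          respiration = 0.3, transp_coef = 2e-4,
                          transp_floor = 2e-4, area_S = 0.36) {
  if (A_max <= 0 || curvature <= 0 || curvature > 1 || respiration < 0) {
    abort("invalid canopy parameters", class = "canopyflux_domain_error")
  }
  structure(list(quantum_yield = quantum_yield, A_max = A_max,
                 curvature = curvature, respiration = respiration,
                 transp_coef = transp_coef, transp_floor = transp_floor,
                 area_S = area_S),
            class = "canopy_params")
}

#' Canopy CO2 source term from PPFD
#'
#' Non-rectangular hyperbola light response minus dark respiration, on the
#' chamber mass-balance sign convention: positive = net CO2 removal (uptake).
#' At PPFD 0 the value is `-respiration`.
#'
#' @param ppfd PPFD, micromol m^-2 s^-1 (vectorised).
#' @param params A [canopy_params()].
#' @return Source term Sx in micromol CO2/s per chamber.
#' @export
canopy_flux <- function(ppfd, params = canopy_params()) {
  stopifnot(inherits(params, "canopy_params"))
  if (any(ppfd < 0)) abort("ppfd must be non-negative",
                           class = "canopyflux_domain_error")
  with(params, {
    I <- ppfd * area_S * quantum_yield
    gross <- (I + A_max - sqrt((I + A_max)^2 - 4 * curvature * I * A_max)) /
      (2 * curvature)
    gross - respiration
  })
}

## gross assimilation (before respiration), used for the transpiration truth
canopy_gross <- function(ppfd, params) {
  canopy_flux(ppfd, params) + params$respiration
}

#' Virtual facility configuration
#'
#' Describes the simulated multi-chamber facility: chamber count and
#' geometry, per-chamber air flux and light treatment, canopy parameters,
#' sensor noise, inter-cell drift, the multiplexer schedule, ambient
#' conditions and the mandatory random seed.
#'
#' @param n_chambers Number of chambers (default 12).
#' @param geometry A [chamber_geometry()].
#' @param F_mol Air flux per chamber, mol/s (recycled to `n_chambers`).
#' @param treatments `"NF"` (non-fluctuating) or `"F"` per chamber; default
#'   alternates.
#' @param canopy A [canopy_params()] or a list of one per chamber.
#' @param light A [light_config()].
#' @param schedule A [sampling_schedule()].
#' @param sigma_co2,sigma_h2o,sigma_flow Gaussian sensor noise SDs (ppm,
#'   mmol/mol, m/s).
#' @param drift_ppm_h Linear inter-cell drift of the sample cell, ppm/h.
#' @param co2_in,h2o_in Buffer air composition (ppm, mmol/mol).
#' @param temp,pressure Chamber air temperature (C) and pressure (Pa).
#' @param duration_s Simulated span, s (default one day).
#' @param seed Integer random seed (mandatory).
#' @return A list of class `facility_config`.
#' @export
facility_config <- function(n_chambers = 12, geometry = chamber_geometry(),
                            F_mol = 0.34,
                            treatments = rep(c("NF", "F"),
                                             length.out = n_chambers),
                            canopy = canopy_params(), light = light_config(),
                            schedule = sampling_schedule(),
                            sigma_co2 = 0.1, sigma_h2o = 0.02,
                            sigma_flow = 0.01, drift_ppm_h = 0.3,
                            co2_in = 400, h2o_in = 10,
                            temp = 25, pressure = 101300,
                            duration_s = 86400, seed) {
  if (missing(seed)) abort("a seed is mandatory for reproducibility",
                           class = "canopyflux_domain_error")
  if (n_chambers < 1 || sigma_co2 < 0 || sigma_h2o < 0 || sigma_flow < 0) {
    abort("invalid facility configuration", class = "canopyflux_domain_error")
  }
  F_mol <- rep(F_mol, length.out = n_chambers)
  treatments <- match.arg(rep(treatments, length.out = n_chambers),
                          c("NF", "F"), several.ok = TRUE)
  if (inherits(canopy, "canopy_params")) {
    canopy <- rep(list(canopy), n_chambers)
  }
  structure(list(n_chambers = n_chambers, geometry = geometry, F_mol = F_mol,
                 treatments = treatments, canopy = canopy, light = light,
                 schedule = schedule, sigma_co2 = sigma_co2,
                 sigma_h2o = sigma_h2o, sigma_flow = sigma_flow,
                 drift_ppm_h = drift_ppm_h, co2_in = co2_in, h2o_in = h2o_in,
                 temp = temp, pressure = pressure, duration_s = duration_s,
                 seed = as.integer(seed)),
            class = "facility_config")
}

## exact update of the first-order chamber balance for a source term held
## constant over each 1-s step: c[i+1] = css[i] + (c[i] - css[i]) exp(-F/V)
chamber_trajectory <- function(Sx, F_mol, V, co2_in, dt = 1, c_init = NULL) {
  a <- exp(-F_mol / V * dt)
  css <- co2_in - Sx / F_mol
  c0 <- c_init %||% css[[1]]
  if (length(Sx) == 1) return(c0)
  x <- (1 - a) * css[-length(css)]
  c(c0, as.numeric(stats::filter(x, a, method = "recursive", init = c0)))
}

#' Simulate the virtual facility
#'
#' Integrates the chamber mass balance for every chamber under its light
#' regime on a 1-s grid (the source term is piecewise constant at that
#' resolution, so the update is exact), then emits the multiplexed logger
#' stream: sequential dwells per chamber, matching events whenever the match
#' interval has elapsed, a sampling line that relaxes exponentially toward
#' the newly selected chamber (time constant `purge_s / 4.6`, ~99 % purged at
#' the end of the purge window), linear inter-cell drift on the sample cell,
#' and independent Gaussian sensor noise. Bit-reproducible for a given seed.
#'
#' @param config A [facility_config()].
#' @return A list with `records` (logger tibble), `truth` (per-second,
#'   per-chamber tibble: `time`, `chamber_id`, `treatment`, `ppfd`,
#'   `true_Sx`, `true_co2_chamber`, `true_E`), and `config`.
#' @export
simulate_facility <- function(config) {
  stopifnot(inherits(config, "facility_config"))
  set.seed(config$seed)
  geom <- config$geometry
  sched <- config$schedule
  times <- seq(0, config$duration_s - 1)

  base <- hourly_ppfd_profile(config$light, times)
  fluct <- fluctuating_profile(base, config$light$fluct_fraction,
                               config$light$fluct_period_s,
                               config$light$waveform)

  ## chamber CO2 trajectories: the outflow carries the transpired water, so
  ## the effective CO2 washout rate is (F - S E)/V; this keeps the emitted
  ## concentrations exactly consistent with the dilution-corrected flux
  ## equations used in processing
  truth <- purrr::map_dfr(seq_len(config$n_chambers), function(ch) {
    ppfd <- if (config$treatments[[ch]] == "F") fluct$ppfd else base$ppfd
    sx <- canopy_flux(ppfd, config$canopy[[ch]])
    gross_area <- canopy_gross(ppfd, config$canopy[[ch]]) / geom$area_S
    e_true <- config$canopy[[ch]]$transp_coef * gross_area +
      config$canopy[[ch]]$transp_floor
    f_eff <- config$F_mol[[ch]] - geom$area_S * e_true
    css <- (config$F_mol[[ch]] * config$co2_in - sx) / f_eff
    a <- exp(-f_eff / geom$content_V)
    co2 <- numeric(length(times))
    co2[[1]] <- css[[1]]
    for (i in seq_along(times)[-1]) {
      co2[[i]] <- css[[i - 1]] + (co2[[i - 1]] - css[[i - 1]]) * a[[i - 1]]
    }
    tibble::tibble(time = times, chamber_id = ch,
                   treatment = config$treatments[[ch]], ppfd = ppfd,
                   true_Sx = sx, true_co2_chamber = co2, true_E = e_true)
  })

  ## dwell plan: cycle chambers, inserting a match dwell when due
  dwells <- list(); t <- 0; ch <- 1; next_match <- sched$match_interval_s
  while (t + sched$dwell_s <= config$duration_s) {
    if (t >= next_match) {
      dwells[[length(dwells) + 1]] <- list(start = t, chamber = 13L)
      next_match <- next_match + sched$match_interval_s
    } else {
      dwells[[length(dwells) + 1]] <- list(start = t, chamber = ch)
      ch <- ch %% config$n_chambers + 1
    }
    t <- t + sched$dwell_s
  }
  plan <- dplyr::bind_rows(dwells)

  rec_time <- unlist(purrr::map(plan$start, ~ .x + seq(0, sched$dwell_s - 1)))
  rec_ch <- rep(plan$chamber, each = sched$dwell_s)
  n <- length(rec_time)

  ## truth seen by the sample line at each emitted second
  idx <- function(ch_vec) (ch_vec - 1L) * config$duration_s + rec_time + 1L
  is_match <- rec_ch == 13L
  h2o_of_E <- function(E, F_mol) {
    (1000 * E * geom$area_S + F_mol * config$h2o_in) / (F_mol + E * geom$area_S)
  }
  tr_co2 <- ifelse(is_match, config$co2_in,
                   truth$true_co2_chamber[idx(pmin(rec_ch, config$n_chambers))])
  F_by_rec <- config$F_mol[pmin(rec_ch, config$n_chambers)]
  tr_h2o <- ifelse(is_match, config$h2o_in,
                   h2o_of_E(truth$true_E[idx(pmin(rec_ch, config$n_chambers))],
                            F_by_rec))
  tr_ppfd <- ifelse(is_match, 0,
                    truth$ppfd[idx(pmin(rec_ch, config$n_chambers))])

  ## sampling line: exponential relaxation toward the selected air, state
  ## carried across valve switches
  tau_line <- sched$purge_s / 4.6
  a_line <- exp(-1 / tau_line)
  line_co2 <- as.numeric(stats::filter((1 - a_line) * tr_co2, a_line,
                                       method = "recursive",
                                       init = tr_co2[[1]]))
  line_h2o <- as.numeric(stats::filter((1 - a_line) * tr_h2o, a_line,
                                       method = "recursive",
                                       init = tr_h2o[[1]]))

  drift <- config$drift_ppm_h * rec_time / 3600
  flow_true <- F_by_rec * phys_constants()$R *
    (config$temp + phys_constants()$zero_celsius) /
    (geom$tube_area * config$pressure)

  records <- tibble::tibble(
    timestamp = rec_time,
    chamber_id = as.integer(rec_ch),
    co2_ref = config$co2_in + stats::rnorm(n, 0, config$sigma_co2),
    co2_sample = line_co2 + drift + stats::rnorm(n, 0, config$sigma_co2),
    h2o_ref = config$h2o_in + stats::rnorm(n, 0, config$sigma_h2o),
    h2o_sample = line_h2o + stats::rnorm(n, 0, config$sigma_h2o),
    flow_velocity = flow_true + stats::rnorm(n, 0, config$sigma_flow),
    temp_chamber = config$temp,
    pressure = config$pressure,
    ppfd_set = tr_ppfd,
    ppfd_transmitted = tr_ppfd,
    mode = ifelse(is_match, "match", "measure")
  )
  list(records = records, truth = truth, config = config)
}

#' True cumulative carbon per chamber
#'
#' Integrates the generator's own source term to grams of carbon per ground
#' area on the micro-meteorological sign convention (net uptake negative),
#' the reference against which processed fluxes are closed.
#'
#' @param truth The `truth` tibble from [simulate_facility()].
#' @param geometry The [chamber_geometry()] used in the simulation.
#' @return A tibble with `chamber_id` and `true_cum_carbon_gC_m2`.
#' @export
true_cumulative_carbon <- function(truth, geometry = chamber_geometry()) {
  truth |>
    dplyr::group_by(.data$chamber_id) |>
    dplyr::summarise(
      true_cum_carbon_gC_m2 = cumulative_carbon(
        .data$time, -.data$true_Sx / geometry$area_S),
      .groups = "drop")
}

#' Synthetic scrub/injection transient fixture
#'
#' Drives one chamber's mass balance with the stepped source term of a
#' reference-flux ramp (soda-lime scrubbing or pure CO2 injection) and
#' returns the Delta-CO2 transient with ground truth, for exercising the
#' transient fitting and validation pipeline without hardware.
#'
#' @param schedule A `ramp_schedule` from [build_ramp_schedule()]; its
#'   `level` column holds pump speeds (l/s for scrub, ml/s for injection).
#' @param mode `"scrub"` (levels are scrub pump speeds) or `"inject"`
#'   (levels are CO2 injection rates).
#' @param F_mol Air flux through the chamber, mol/s.
#' @param geometry A [chamber_geometry()].
#' @param co2_in Buffer CO2, ppm.
#' @param t0,tau Dead time (s) and residence-time multiplier applied to the
#'   emitted trace (truth for delay-correction tests); `t0` shifts the trace,
#'   `tau` scales the mixing rate.
#' @param noise_sd Gaussian noise SD on Delta-CO2, ppm.
#' @param temp,pressure Conditions for the reference-flux formulas.
#' @param seed Seed for the noise.
#' @return A tibble with `time`, `delta_co2` (noisy), `delta_co2_true`,
#'   `Sx_true` (micromol/s), `A_ref` (the reference flux in micromol m^-2
#'   s^-1, negative for scrub), `level`.
#' @export
make_scrub_fixture <- function(schedule, mode = c("scrub", "inject"),
                               F_mol = 0.34, geometry = chamber_geometry(),
                               co2_in = 410, t0 = 0, tau = 1, noise_sd = 0,
                               temp = 25, pressure = 101300, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "ramp_schedule"))
  set.seed(seed)
  total <- max(schedule$end_s)
  times <- seq(0, total - 1)
  level_t <- ramp_level_at(schedule, times)
  A_ref_t <- if (mode == "scrub") {
    simulated_photosynthesis(level_t, pressure, temp, co2_chamber = co2_in,
                             area_S = geometry$area_S)
  } else {
    simulated_respiration(level_t, pressure, temp, geometry$area_S)
  }
  sx_t <- -A_ref_t * geometry$area_S   # model sign: removal positive

  ## tau scales the effective mixing rate; t0 delays the observed trace
  ## (the chamber starts at the buffer concentration, i.e. S0 = 0)
  co2 <- chamber_trajectory(sx_t, F_mol, geometry$content_V / tau, co2_in,
                            c_init = co2_in)
  delta_true <- co2_in - co2
  obs_idx <- pmax(1, seq_along(times) - round(t0))
  delta_obs <- delta_true[obs_idx]
  tibble::tibble(
    time = times,
    delta_co2 = delta_obs + stats::rnorm(length(times), 0, noise_sd),
    delta_co2_true = delta_obs,
    Sx_true = sx_t,
    A_ref = A_ref_t,
    level = level_t
  )
}
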