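test_that("simulated photosynthesis evaluates both conventions", {
  expect_equal(simulated_photosynthesis(0, co2_chamber = 410), 0)
  # physical mode: pumped molar flow times chamber CO2 per ground area
  n <- 0.2e-3 * 101300 / (8.3144598 * 298.15)
  expect_equal(simulated_photosynthesis(0.2, 101300, 25, co2_chamber = 410),
               -n * 410 / 0.36, tolerance = 1e-10)
  # literal historical form
  expect_equal(simulated_photosynthesis(0.2, 101300, 25, mode = "as_printed"),
               -1000 * n, tolerance = 1e-10)
  expect_error(simulated_photosynthesis(0.2),
               class = "canopyflux_missing_parameter_error")
})

test_that("scrub fluxes over the protocol stay inside the validated range", {
  speeds <- seq(0.02, 0.2, length.out = 6)
  a_phys <- simulated_photosynthesis(speeds, co2_chamber = 410)
  a_lit <- simulated_photosynthesis(speeds, mode = "as_printed")
  expect_true(all(abs(a_phys) <= 10))
  expect_true(all(abs(a_lit) <= 10))
  expect_true(all(a_phys < 0))
})

test_that("simulated respiration is linear in the injected flux", {
  expect_equal(simulated_respiration(0), 0)
  expect_equal(simulated_respiration(0.1),
               0.1 * 101300 / (0.36 * 298.15 * 8.3144598), tolerance = 1e-12)
  expect_equal(simulated_respiration(0.2), 2 * simulated_respiration(0.1))
  expect_gt(simulated_respiration(0.1), 0)
})

test_that("ramp schedules ascend then descend with the peak in both passes", {
  sch <- build_ramp_schedule(seq(0.02, 0.2, length.out = 6), 600, 60)
  expect_equal(nrow(sch), 12L)
  expect_equal(max(sch$end_s), 7200)
  expect_equal(sch$level, c(seq(0.02, 0.2, length.out = 6),
                            rev(seq(0.02, 0.2, length.out = 6))))
  one <- build_ramp_schedule(0.1)
  expect_equal(nrow(one), 2L)
  # level lookup returns the enclosing step's level
  expect_equal(ramp_level_at(sch, c(0, 599, 600, 7199)),
               c(0.02, 0.02, 0.056, 0.02))
  expect_error(build_ramp_schedule(c(0.2, 0.1)),
               class = "canopyflux_domain_error")
  expect_error(build_ramp_schedule(0.1, step_duration_s = 50,
                                   extraction_window_s = 60),
               class = "canopyflux_domain_error")
})

test_that("step extraction means the last window of each settled step", {
  sch <- build_ramp_schedule(c(0.05, 0.1), 600, 60)
  tt <- seq(0, 2400 - 1)
  # constant series: every step mean equals the constant
  out <- extract_step_fluxes(tt, rep(-3, length(tt)), sch)
  expect_equal(out$mean_flux, rep(-3, 4))
  expect_true(all(out$n_samples >= 59))
  # extraction window longer than the step is an error
  expect_error(extract_step_fluxes(tt, rep(-3, length(tt)), sch,
                                   extraction_window_s = 700),
               class = "canopyflux_domain_error")
  # ramp through the chamber model: last-60-s means sit at the closed-form
  # steady state (steps are much longer than the settling time)
  fx <- make_scrub_fixture(sch, "scrub", F_mol = 0.4, co2_in = 410)
  steps <- extract_step_fluxes(fx$time, fx$delta_co2, sch)
  for (i in seq_len(nrow(steps))) {
    sx <- -simulated_photosynthesis(steps$level[[i]],
                                    co2_chamber = 410) * 0.36
    expect_equal(steps$mean_flux[[i]], sx / 0.4, tolerance = 0.01)
  }
})

test_that("normalized ramps collapse onto a common settling shape", {
  sch <- build_ramp_schedule(0.1, 900, 60)
  # two air fluxes: higher F settles faster
  n_of <- function(f) {
    fx <- make_scrub_fixture(sch, "scrub", F_mol = f, co2_in = 410)
    one <- fx[fx$time < 900, ]
    normalize_ramps(one$delta_co2, one$Sx_true[[1]], 0)
  }
  n_lo <- n_of(0.2); n_hi <- n_of(0.6)
  expect_equal(range(n_lo), c(0, 1))
  expect_equal(range(n_hi), c(0, 1))
  # the normalized trajectory decays as exp(-(F/V) t) for each F
  tt <- seq(0, 899)
  expect_equal(n_lo, exp(-0.2 / 19.3 * tt), tolerance = 0.01)
  expect_equal(n_hi, exp(-0.6 / 19.3 * tt), tolerance = 0.01)
  # settling ordering: the high-F curve decays faster everywhere
  expect_true(all(n_hi - n_lo <= 1e-9))
  # time to settle (drop below 5 % of the step) is shorter at higher F
  expect_lt(min(tt[n_hi <= 0.05]), min(tt[n_lo <= 0.05]))
  expect_error(normalize_ramps(c(1, 2), 3, 3),
               class = "canopyflux_domain_error")
  expect_error(normalize_ramps(rep(1, 5), 3, 0),
               class = "canopyflux_degenerate_error")
})

test_that("validation regression recovers identity for self-consistent data", {
  expect_error(validation_regression(1:2, 1:2),
               class = "canopyflux_domain_error")
  r <- suppressWarnings(validation_regression(c(-1, 0, 2, 5), c(-1, 0, 2, 5)))
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r.squared, 1, tolerance = 1e-12)
})

test_that("the full scrub + injection campaign regresses to slope 1", {
  geom <- chamber_geometry()
  # scrub ramp at the six protocol pump speeds
  sch_s <- build_ramp_schedule(seq(0.02, 0.2, length.out = 6), 600, 60)
  fx_s <- make_scrub_fixture(sch_s, "scrub", F_mol = 0.34, co2_in = 410)
  A_s <- -0.34 * fx_s$delta_co2 / geom$area_S
  st_s <- extract_step_fluxes(fx_s$time, A_s, sch_s)
  sim_s <- simulated_photosynthesis(st_s$level, co2_chamber = 410)
  # injection ramp
  sch_i <- build_ramp_schedule(seq(0.02, 0.1, length.out = 5), 600, 60)
  fx_i <- make_scrub_fixture(sch_i, "inject", F_mol = 0.34, co2_in = 410)
  A_i <- -0.34 * fx_i$delta_co2 / geom$area_S
  st_i <- extract_step_fluxes(fx_i$time, A_i, sch_i)
  sim_i <- simulated_respiration(st_i$level)
  reg <- validation_regression(c(st_s$mean_flux, st_i$mean_flux),
                               c(sim_s, sim_i))
  expect_gt(reg$slope, 0.99); expect_lt(reg$slope, 1.01)
  expect_gt(reg$r.squared, 0.999)
  expect_lt(reg$p.value, 1e-6)
  # fluxes span both signs like the instrument validation
  expect_lt(min(sim_s), 0); expect_gt(max(sim_i), 0)
})
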