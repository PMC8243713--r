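test_that("noiseless transients are recovered to solver tolerance", {
  p <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3,
                        t0 = 110, tau = 0.8)
  tt <- seq(0, 400)
  d <- delta_co2_closed_form(p, tt)
  fit <- fit_transient(tt, d, 0.34, 19.3)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_true(fit$converged)
  expect_equal(est[["Sx"]], 3, tolerance = 1e-6)
  expect_equal(est[["S0"]], 0, tolerance = 1e-6)
  expect_equal(est[["t0"]], 110, tolerance = 1e-4)
  expect_equal(est[["tau"]], 0.8, tolerance = 1e-6)
})

test_that("flat traces and undersized data are rejected", {
  expect_error(fit_transient(1:100, rep(2, 100), 0.34, 19.3),
               class = "canopyflux_degenerate_error")
  expect_error(fit_transient(1:3, c(1, 2, 3), 0.34, 19.3),
               class = "canopyflux_degenerate_error")
})

test_that("fits are invariant to time-axis translation when t0 is free", {
  p <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0.5, Sx = 3,
                        t0 = 60, tau = 1.2)
  tt <- seq(0, 350)
  d <- delta_co2_closed_form(p, tt)
  f1 <- fit_transient(tt, d, 0.34, 19.3)
  f2 <- fit_transient(tt + 500, d, 0.34, 19.3)
  sx1 <- f1$estimates$estimate[f1$estimates$term == "Sx"]
  sx2 <- f2$estimates$estimate[f2$estimates$term == "Sx"]
  expect_equal(sx1, sx2, tolerance = 1e-6)
  tau1 <- f1$estimates$estimate[f1$estimates$term == "tau"]
  tau2 <- f2$estimates$estimate[f2$estimates$term == "tau"]
  expect_equal(tau1, tau2, tolerance = 1e-5)
})

test_that("noisy fits recover Sx without bias (seeded replicates)", {
  p <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3,
                        t0 = 0, tau = 1)
  tt <- seq(0, 279)
  d0 <- delta_co2_closed_form(p, tt)
  set.seed(123)
  ests <- replicate(60, {
    fit <- fit_transient(tt, d0 + rnorm(length(tt), 0, 0.1), 0.34, 19.3,
                         free = c("Sx", "S0", "tau"))
    fit$estimates$estimate[fit$estimates$term == "Sx"]
  })
  se_mean <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - 3), 2 * se_mean + 1e-3)
})

test_that("steady state is recovered from a window truncated before settling", {
  # truth settles after ~300 s; data end at 180 s
  p <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3,
                        t0 = 0, tau = 0.9)
  tt <- seq(0, 180)
  d <- delta_co2_closed_form(p, tt)
  ss <- estimate_steady_state(tt, d, 0.34, 19.3, window = c(60, 180))
  expect_equal(ss$delta_co2_ss, 3 / 0.34, tolerance = 1e-4)
  # the raw window mean is far off (the naive estimate is biased)
  expect_gt(abs(mean(d[tt >= 60]) - 3 / 0.34) / (3 / 0.34), 0.1)
  # a window on the flat pre-step is degenerate
  flat <- rep(0, 181)
  expect_error(estimate_steady_state(tt, flat, 0.34, 19.3,
                                     window = c(0, 50)),
               class = "canopyflux_degenerate_error")
})

test_that("steady-state intervals have near-nominal coverage (seeded)", {
  p <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 3,
                        t0 = 0, tau = 1)
  tt <- seq(0, 180)
  d0 <- delta_co2_closed_form(p, tt)
  truth <- 3 / 0.34
  set.seed(2024)
  hits <- replicate(100, {
    ss <- estimate_steady_state(tt, d0 + rnorm(length(tt), 0, 0.1),
                                0.34, 19.3, window = c(60, 180))
    ss$conf.low <= truth && truth <= ss$conf.high
  })
  expect_gte(mean(hits), 0.90)
})

test_that("daily delay correction removes the tau/t0 bias of naive estimates", {
  geom <- chamber_geometry()
  sch <- build_ramp_schedule(c(0.2), 600, 60)
  cal <- make_scrub_fixture(sch, "scrub", F_mol = 0.34, co2_in = 410,
                            t0 = 110, tau = 0.7)
  cal_one <- cal[cal$time < 600, ]
  # measurement windows: steady-state segments of known Sx
  p_true <- transient_params(F_mol = 0.34, V = 19.3, S0 = 0, Sx = 2.5,
                             t0 = 110, tau = 0.7)
  t_rel <- seq(120, 290)
  meas <- tibble::tibble(window_id = 1L, t_rel = t_rel,
                         delta_co2 = delta_co2_closed_form(p_true, t_rel))
  out <- daily_delay_correction(cal_one, meas, 0.34, 19.3)
  expect_true(out$corrected[[1]])
  expect_equal(out$Sx_corrected[[1]], 2.5, tolerance = 0.02)
  # the naive estimate on the same unsteady window is biased
  naive <- mean(meas$delta_co2) * 0.34
  expect_gt(abs(naive - 2.5) / 2.5,
            abs(out$Sx_corrected[[1]] - 2.5) / 2.5)
  # fitted delay parameters match the generator truth
  expect_equal(attr(out, "tau"), 0.7, tolerance = 0.05)
  expect_equal(attr(out, "t0"), 110, tolerance = 5)
})

test_that("failed calibration falls back to naive estimates with a warning", {
  flat_cal <- tibble::tibble(time = 1:50, delta_co2 = rep(1, 50))
  meas <- tibble::tibble(window_id = 1L, t_rel = seq(150, 290),
                         delta_co2 = 8.8)
  expect_warning(out <- daily_delay_correction(flat_cal, meas, 0.34, 19.3),
                 "uncorrected")
  expect_false(out$corrected[[1]])
  expect_equal(out$Sx_corrected[[1]], 8.8 * 0.34, tolerance = 1e-9)
})

test_that("tidy and glance expose the broom-style summaries", {
  p <- default_params(tau = 1.1)
  tt <- seq(0, 300)
  fit <- fit_transient(tt, delta_co2_closed_form(p, tt), 0.34, 19.3,
                       free = c("Sx", "tau"), init = list(S0 = 0))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std.error"))
  gl <- glance(fit)
  expect_equal(gl$n_points, 301L)
  expect_equal(gl$delta_co2_ss, 3 / 0.34, tolerance = 1e-5)
  expect_s3_class(autoplot(fit), "ggplot")
})
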