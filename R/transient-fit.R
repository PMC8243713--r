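## closed-form transient as a plain function of a named parameter vector,
## time measured on the same axis as the data
transient_model <- function(t, p, F_mol, V) {
  expo <- exp(-(F_mol / V) * p[["tau"]] * pmax(t - p[["t0"]], 0))
  (p[["Sx"]] + (p[["S0"]] - p[["Sx"]]) * expo) / F_mol
}

#' Fit the chamber transient to measured Delta-CO2
#'
#' Nonlinear least-squares fit of the residence-time-corrected chamber
#' transient to a measured Delta-CO2 trace, estimating any subset of
#' \{`Sx`, `S0`, `t0`, `tau`\} with the others held fixed. `F_mol` and `V`
#' are always known (flow meter and chamber geometry).
#'
#' Default initial guesses: `S0` from the first five points, `Sx` from the
#' last five, `t0` from the first point deviating more than three noise
#' standard deviations from the initial plateau, `tau = 1`. Default bounds
#' keep the exponent identifiable: `tau` in \[0.05, 20\], `t0` within the data
#' span.
#'
#' @param times Measurement times, s.
#' @param delta_co2 Measured inlet-minus-chamber CO2, ppm.
#' @param F_mol Molar air flux, mol/s.
#' @param V Chamber content, mol.
#' @param free Character vector of parameters to estimate.
#' @param init Named list overriding the automatic initial values (also used
#'   as the fixed value for parameters not in `free`).
#' @param bounds Named list of `c(lower, upper)` pairs overriding defaults.
#' @param robust If `TRUE`, minimise a soft-L1 loss instead of squared
#'   residuals (standard errors are then not reported).
#' @param average_5s If `TRUE`, average the trace into 5-s bins before
#'   fitting.
#' @return An object of class `transient_fit`; see [tidy.transient_fit()].
#'   `t0` is estimated and reported relative to the first fitted sample.
#' @export
fit_transient <- function(times, delta_co2, F_mol, V,
                          free = c("Sx", "S0", "t0", "tau"),
                          init = list(), bounds = list(),
                          robust = FALSE, average_5s = FALSE) {
  stopifnot(length(times) == length(delta_co2))
  free <- match.arg(free, c("Sx", "S0", "t0", "tau"), several.ok = TRUE)
  if (average_5s) {
    bin <- floor((times - min(times)) / 5)
    times <- tapply(times, bin, mean)
    delta_co2 <- tapply(delta_co2, bin, mean)
    times <- as.numeric(times); delta_co2 <- as.numeric(delta_co2)
  }
  if (length(times) <= length(free)) {
    abort("need more points than free parameters",
          class = "canopyflux_degenerate_error")
  }
  if (sd(delta_co2) == 0) {
    abort("trace is constant: no transient to fit",
          class = "canopyflux_degenerate_error")
  }
  ## fit on a window-relative time axis so estimates (t0 in particular) are
  ## invariant to time-axis translation; t0 is reported relative to the
  ## first fitted sample
  t_origin <- min(times)
  times <- times - t_origin

  n5 <- min(5, length(delta_co2))
  s0_guess <- mean(head(delta_co2, n5)) * F_mol
  sx_guess <- mean(tail(delta_co2, n5)) * F_mol
  noise <- max(sd(head(delta_co2, n5)), 1e-6)
  dev <- which(abs(delta_co2 - s0_guess / F_mol) > 3 * noise)
  t0_guess <- if (length(dev) > 0) times[[dev[[1]]]] else 0
  span <- max(times) - min(times)

  ## the data-driven t0 guess is only an initial value when t0 is free;
  ## a fixed, unspecified t0 defaults to 0 (and tau to 1, perfect mixing)
  p0 <- list(Sx = sx_guess, S0 = s0_guess,
             t0 = if ("t0" %in% free) t0_guess else 0, tau = 1)
  p0[names(init)] <- init
  default_bounds <- list(Sx = c(-Inf, Inf), S0 = c(-Inf, Inf),
                         t0 = c(0, span), tau = c(0.05, 20))
  default_bounds[names(bounds)] <- bounds

  fixed <- setdiff(c("Sx", "S0", "t0", "tau"), free)
  start <- unlist(p0[free])
  lower <- vapply(free, function(nm) default_bounds[[nm]][[1]], 0)
  upper <- vapply(free, function(nm) default_bounds[[nm]][[2]], 0)
  start <- pmin(pmax(start, lower), upper)
  full_par <- function(th) {
    p <- p0
    p[free] <- as.list(th)
    unlist(p)
  }

  est <- start; se <- rep(NA_real_, length(free)); converged <- FALSE
  if (robust) {
    soft_l1 <- function(th) {
      r <- delta_co2 - transient_model(times, full_par(th), F_mol, V)
      sum(2 * (sqrt(1 + r^2) - 1))
    }
    opt <- stats::optim(start, soft_l1, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 500))
    est <- opt$par
    converged <- opt$convergence == 0
  } else {
    resid_fn <- function(th) {
      delta_co2 - transient_model(times, full_par(th), F_mol, V)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est <- fit$par
      converged <- fit$info %in% 1:4
      dfree <- length(times) - length(free)
      sigma2 <- fit$deviance / max(dfree, 1)
      se <- tryCatch(sqrt(diag(sigma2 * solve(fit$hessian))),
                     error = function(e) se)
    }
  }
  names(est) <- free
  p_hat <- full_par(est)
  resid <- delta_co2 - transient_model(times, p_hat, F_mol, V)

  structure(list(
    estimates = tibble::tibble(term = free, estimate = unname(est),
                               std.error = unname(se)),
    params = p_hat, fixed = fixed,
    F_mol = F_mol, V = V,
    rss = sum(resid^2), n_points = length(times),
    converged = converged, robust = robust,
    window = c(t_origin, t_origin + max(times)),
    data = tibble::tibble(time = times + t_origin, delta_co2 = delta_co2,
                          fitted = transient_model(times, p_hat, F_mol, V))
  ), class = "transient_fit")
}

#' @export
print.transient_fit <- function(x, ...) {
  cat("Chamber transient fit (", x$n_points, " points, window ",
      round(x$window[[1]], 1), "-", round(x$window[[2]], 1), " s)\n", sep = "")
  cat(if (x$converged) "converged" else "NOT converged",
      "; RSS = ", signif(x$rss, 4), "\n", sep = "")
  print(x$estimates)
  invisible(x)
}

#' Tidy a chamber transient fit
#'
#' @param x A `transient_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`.
#' @method tidy transient_fit
#' @export
tidy.transient_fit <- function(x, ...) x$estimates

#' One-row summary of a chamber transient fit
#'
#' @param x A `transient_fit` object.
#' @param ... Unused.
#' @return A tibble with `rss`, `sigma`, `n_points`, `df.residual`,
#'   `converged`, and the steady-state estimate `delta_co2_ss = Sx/F`.
#' @method glance transient_fit
#' @export
glance.transient_fit <- function(x, ...) {
  df <- x$n_points - nrow(x$estimates)
  tibble::tibble(
    rss = x$rss, sigma = sqrt(x$rss / max(df, 1)),
    n_points = x$n_points, df.residual = df, converged = x$converged,
    delta_co2_ss = x$params[["Sx"]] / x$F_mol
  )
}

#' Extrapolate steady-state Delta-CO2 from an unsteady window
#'
#' Fits the residence-time-corrected transient on a window of the trace
#' (e.g. 60-180 s, long before settling) and returns the asymptote `Sx/F`
#' with a delta-method confidence interval. This recovers the steady state a
#' fluctuating canopy never actually reaches.
#'
#' Within the window the dead time is absorbed into the amplitude, so the
#' identifiable free set `{Sx, S0, tau}` is fitted with `t0` fixed at the
#' window start.
#'
#' @param times,delta_co2,F_mol,V As in [fit_transient()].
#' @param window `c(start, end)` in seconds on the `times` axis.
#' @param level Confidence level.
#' @param ... Passed to [fit_transient()].
#' @return A tibble with `delta_co2_ss`, `conf.low`, `conf.high`, `Sx`,
#'   `std.error_Sx`, `converged`.
#' @export
estimate_steady_state <- function(times, delta_co2, F_mol, V,
                                  window = c(60, 180), level = 0.95, ...) {
  keep <- times >= window[[1]] & times <= window[[2]]
  if (sum(keep) < 4) {
    abort("window contains too few points", class = "canopyflux_domain_error")
  }
  fit <- fit_transient(times[keep], delta_co2[keep], F_mol, V,
                       free = c("Sx", "S0", "tau"),
                       init = list(t0 = 0), ...)
  sx <- fit$params[["Sx"]]
  se <- fit$estimates$std.error[fit$estimates$term == "Sx"]
  dfree <- fit$n_points - nrow(fit$estimates)
  q <- qt(1 - (1 - level) / 2, dfree)
  tibble::tibble(
    delta_co2_ss = sx / F_mol,
    conf.low = (sx - q * se) / F_mol,
    conf.high = (sx + q * se) / F_mol,
    Sx = sx, std.error_Sx = se, converged = fit$converged
  )
}

#' Daily delay correction of measured source terms
#'
#' Estimates the residence-time multiplier `tau` and dead time `t0` from a
#' calibration transient (a scrub or injection event run once per day), then
#' inverts the transient with those values for every measurement window of
#' the day. If the calibration fit fails, the naive steady-state estimate
#' `delta_co2 * F` is returned with a warning.
#'
#' @param calibration Tibble with columns `time` (s) and `delta_co2` (ppm)
#'   for the calibration event.
#' @param measurements Tibble with columns `window_id`, `t_rel` (seconds
#'   since the window's step) and `delta_co2`.
#' @param F_mol,V Flow and chamber content.
#' @param S0 Source term at each window's start (default 0).
#' @return A tibble with `window_id`, `Sx_corrected` (micromol/s),
#'   `n_samples`, `corrected` (logical), plus the fitted `tau` and `t0` as
#'   attributes `"tau"` and `"t0"`.
#' @export
daily_delay_correction <- function(calibration, measurements, F_mol, V,
                                   S0 = 0) {
  fit <- tryCatch(
    fit_transient(calibration$time, calibration$delta_co2, F_mol, V,
                  free = c("Sx", "S0", "t0", "tau")),
    error = function(e) NULL)
  ok <- !is.null(fit) && fit$converged
  if (!ok) {
    warn("calibration fit failed; returning uncorrected (naive) source terms")
    out <- measurements |>
      dplyr::group_by(.data$window_id) |>
      dplyr::summarise(Sx_corrected = mean(.data$delta_co2) * F_mol,
                       n_samples = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(corrected = FALSE)
    attr(out, "tau") <- NA_real_; attr(out, "t0") <- NA_real_
    return(out)
  }
  tau_hat <- fit$params[["tau"]]; t0_hat <- fit$params[["t0"]]
  p <- transient_params(F_mol = F_mol, V = V, S0 = S0, Sx = 0,
                        t0 = t0_hat, tau = tau_hat)
  out <- measurements |>
    dplyr::filter(.data$t_rel > t0_hat) |>
    dplyr::group_by(.data$window_id) |>
    dplyr::summarise(
      Sx_corrected = mean(invert_for_sx(.data$delta_co2, p, .data$t_rel)),
      n_samples = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(corrected = TRUE)
  attr(out, "tau") <- tau_hat; attr(out, "t0") <- t0_hat
  out
}
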