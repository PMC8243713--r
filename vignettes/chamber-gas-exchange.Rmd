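---
title: "Open-chamber canopy gas exchange: model, estimation and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-chamber canopy gas exchange: model, estimation and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyflux)
```

`canopyflux` processes data from multiplexed open-chamber gas-exchange
facilities: a single differential gas analyzer is switched sequentially
across a set of growth chambers, and whole-canopy CO2 and H2O fluxes are
derived from the concentration differences between each chamber and the
common buffer (inlet) air. This vignette describes the models the package
implements, the estimation choices, the synthetic facility used for testing,
and the package's known limitations.

## Flux equations

For a chamber of ground area $S$ (m$^2$) ventilated by a molar air flux
$air_{flow}$ (mol s$^{-1}$), evapotranspiration and net CO2 exchange per
ground area are

$$E = air_{flow}\,\frac{H_2O_{chamber} - H_2O_{in}}{S\,(1000 - H_2O_{chamber})},
\qquad
A = air_{flow}\,\frac{CO_{2,chamber} - CO_{2,in}}{S} - CO_{2,chamber}\,E,$$

with H2O in mmol mol$^{-1}$, CO2 in µmol mol$^{-1}$, $E$ in
mol H2O m$^{-2}$ s$^{-1}$ and $A$ in µmol CO2 m$^{-2}$ s$^{-1}$. The second
term of $A$ removes the apparent CO2 flux created by water vapour dilution.
The micro-meteorological sign convention is used throughout: net uptake is
negative. The measured duct velocity (m s$^{-1}$) is converted to mol
s$^{-1}$ with the ideal gas law via `air_flow_molar()`; the flow
transmitters themselves are calibrated against a reference mass flow meter
by ordinary least squares (`fit_linear_calibration()`).

## Chamber mass balance

A well-mixed chamber holding $V$ mol of air with source term $S_x$
(µmol s$^{-1}$, positive when the canopy removes CO2) obeys

$$\frac{dCO_{2,chamber}}{dt} =
  \frac{F \cdot CO_{2,in} - S_x}{V} - \frac{F \cdot CO_{2,chamber}}{V}.$$

For a step in $S_x$ the solution for
$\Delta CO_2 = CO_{2,in} - CO_{2,chamber}$ is the exponential

$$\Delta CO_2(t) = \frac{1}{F}\left(S_x + (S_0 - S_x)\,
  e^{-\frac{F}{V}\tau\,(t - t_0)}\right),$$

where $t_0$ is the dead time (tubing plus chamber response) and $\tau$ a
unitless residence-time multiplier ($\tau = 1$ means perfect mixing; the
multiplier rescales the whole exponent, the only reading under which it is
dimensionless). Inverting for the source term gives

$$S_x = \frac{\Delta CO_2 \cdot F}{1 - e^{-\frac{F}{V}\tau(t-t_0)}}
      - \frac{S_0\,e^{-\frac{F}{V}\tau(t-t_0)}}{1 - e^{-\frac{F}{V}\tau(t-t_0)}}.$$

$\Delta CO_2$ is defined as inlet minus chamber throughout, so a scrub or
photosynthesis event produces a positive transient; the conversion to the
signed flux $A$ happens only in the flux engine. With $F = 0.34$ mol
s$^{-1}$ and $V = 19.3$ mol the 0.5 % settling time
$\frac{V}{F}\ln(1/0.005)$ is about 300 s — longer than a typical dwell,
which is why the transient machinery below matters. (Some hardware
descriptions quote the chamber as 0.54 m$^3$, which at laboratory
conditions would hold ~22 mol; the molar content 19.3 mol is taken as
authoritative for the model and the discrepancy is simply documented.)
Likewise the model adopts mol s$^{-1}$ for $F$: 0.34 mol s$^{-1}$
reproduces the observed ~300 s settling, whereas reading the same figure
as litres per second would imply a ~23 min settling time.

`integrate_chamber()` solves the ODE under arbitrary forcing with an
adaptive-step solver (relative tolerance $10^{-8}$), and agreement with the
closed form under constant forcing to $10^{-6}$ relative is enforced by
test — the module's central oracle equivalence.

## Estimating tau, t0 and steady state from transients

`fit_transient()` fits the $\tau$-corrected exponential to a measured
$\Delta CO_2$ trace by bounded Levenberg–Marquardt least squares, with any
subset of $\{S_x, S_0, t_0, \tau\}$ free. Choices worth knowing:

* **Initialisation.** $S_0$ from the first five points, $S_x$ from the last
  five, $t_0$ from the first point deviating more than three noise standard
  deviations from the initial plateau, $\tau = 1$. A parameter that is held
  fixed but not supplied defaults to $t_0 = 0$, $\tau = 1$.
* **Bounds.** $\tau \in [0.05, 20]$ and $t_0$ within the window keep the
  exponent identifiable; $S_x$ and $S_0$ are unbounded.
* **Time axis.** Fitting is done on a window-relative axis, so estimates are
  invariant to time translation; $t_0$ is reported relative to the first
  fitted sample.
* **Loss.** Unweighted squared residuals by default; a soft-L1 option exists
  for spike-contaminated traces (without standard errors). Fitting 5-s
  averaged traces is available but off by default — averaging is
  presentation, not method.
* **Non-convergence** is flagged in the returned object, not raised, so a
  day of windows can be processed unattended; degenerate (flat) traces do
  raise an error.

`estimate_steady_state()` fits a window of the rising transient (60–180 s
by default, well before settling) and returns the asymptote $\hat S_x / F$
with a delta-method confidence interval. Within such a window the dead time
is absorbed into the exponential amplitude, so the identifiable free set
$\{S_x, S_0, \tau\}$ is fitted with $t_0$ pinned to the window start.
Whether $S_0$ should be fixed to the pre-step baseline or estimated is
genuinely open; both modes are provided (`init = list(S0 = ...)` fixes it).

`daily_delay_correction()` implements the daily calibration routine: a
scrub or injection event is fitted for $\tau$ and $t_0$ once per day (canopy
growth changes chamber mixing over time), and every measurement window of
that day is then inverted with those values. If the calibration fit fails
the naive steady-state estimate $\Delta CO_2 \cdot F$ is passed through with
a warning rather than silently inventing a correction.

## Error propagation

Treating the measured variables as independent, the uncertainty of the
inverted source term is propagated through the partial derivatives of the
inversion:

$$T = \sqrt{\left(\frac{\partial S_x}{\partial F}\bar F\right)^2 +
            \left(\frac{\partial S_x}{\partial S_0}\bar S_0\right)^2 +
            \left(\frac{\partial S_x}{\partial \Delta CO_2}\overline{\Delta CO_2}\right)^2 +
            \left(\frac{\partial S_x}{\partial t_0}\bar t_0\right)^2}.$$

The default ranges are the system's operating spans: $F$ 0.2–0.6 mol
s$^{-1}$, $S_0$ 0–5 µmol s$^{-1}$, $t_0$ 0–100 s, $\Delta CO_2$ 0–10 ppm.
The weights $\bar v$ are interpreted as the magnitude of the considered
parameter change; `sensitivity_sweep()` evaluates them on a grid from zero
to the full range width, reported as a normalized 0–100 % change, as a
percentage of a nominal $S_x$ (default 3 µmol s$^{-1}$, mid-scale of the
validated ±10 µmol m$^{-2}$ s$^{-1}$ flux range over a 0.36 m$^2$ chamber).
Partials are evaluated by default at steady state ($t - t_0 = 10V/F$) at
the system's operating point $F = 0.34$ mol s$^{-1}$; there the $S_0$ and
$t_0$ contributions are exponentially suppressed (each far below 1 % of
$S_x$) and the $F$ component is the largest single contributor to $T$,
slightly ahead of the $\Delta CO_2$ term. That ordering is evaluation-point
dependent — at a hypothetical operating flux of 0.6 mol s$^{-1}$ the
$\Delta CO_2$ term would overtake it — and how per-chamber values should be
aggregated is not uniquely determined, so the sweep exposes $F$ as the
per-chamber variable and leaves aggregation to the caller.

```{r sweep}
sensitivity_sweep(grid_points = 3, nominal_Sx = 3, F_mol = 0.34)
```

## Reference-flux calibration

Known fluxes are created physically: scrubbing chamber air through soda
lime at pump speed $scrub_{flux}$ (l s$^{-1}$) simulates photosynthesis;
injecting pure CO2 (ml s$^{-1}$) simulates respiration
(`simulated_photosynthesis()`, `simulated_respiration()`). The respiration
formula is dimensionally exact as written (the ml-to-m$^3$ and mol-to-µmol
factors cancel). The historical photosynthesis formula, however, omits the
chamber CO2 concentration and area; the package therefore defaults to a
`physical` mode — the scrubber removes the CO2 carried by its pumped air,
assuming 100 % scrub efficiency:
$A_{sim} = -\,n \cdot CO_{2,chamber}/S$ with
$n = scrub_{flux} \cdot 10^{-3} P / (R(T+273.15))$ — and offers the literal
form as `as_printed`. Both stay within the validated ±10 µmol m$^{-2}$
s$^{-1}$ range over the protocol speeds (0.02–0.2 l s$^{-1}$), so downstream
conclusions do not depend on the choice.

The protocol (`build_ramp_schedule()`) holds each of six levels for 10 min,
ascending then descending; fluxes are extracted as the mean over the last
60 s of each step (`extract_step_fluxes()`), and measured-versus-simulated
accuracy is summarised by an ordinary least-squares regression
(`validation_regression()`, with the usual two-sided t-test on the slope).
`normalize_ramps()` rescales transients by $S_x/(S_0 - S_x)$ followed by
min–max normalization so ramps at different pump speeds collapse onto their
common exponential shape; higher air flux settles visibly faster.

## Light regimes

`daily_ppfd_profile()` builds a clear-day PPFD curve from standard solar
geometry (declination $23.44^\circ \sin(2\pi(284+N)/365)$, hour angle from
local solar time), scaled so solar noon equals `ppfd_max` exactly. No
equation-of-time or timezone correction is applied — the chamber simulation
needs the shape, not astronomical precision. The facility's light
controller updates once per clock hour, so `hourly_ppfd_profile()` holds
the hour-start value: that stepped profile is the non-fluctuating (NF)
treatment, and the fluctuating (F) treatment oscillates around the same
hourly value — which is also why the NF profile is read as hourly-stepped:
the fluctuations are defined "around the hourly value" of NF.
`fluctuating_profile()` defaults to a square wave (two-level stepping, the
form observable in practice; a sine is available) of ±50 % with a 120-s
period. Because 3600 s is an integer number of periods and the two half
periods are equal, every hour of the F profile averages exactly to the NF
value, so both treatments deliver the same daily light integral by
construction — the design requirement that makes the two treatments
comparable.

## The virtual facility

`simulate_facility()` makes every stage testable without hardware. Per
chamber, a non-rectangular hyperbola with dark respiration (defaults:
quantum yield 0.05 µmol CO2 per µmol photons, gross capacity 4 µmol
s$^{-1}$ per chamber, curvature 0.8, respiration 0.3 µmol s$^{-1}$) maps
PPFD to the source term. These defaults put the midday 500–1500 µmol
m$^{-2}$ s$^{-1}$ fluctuations into the saturated range of the response —
the regime in which fluctuating light is expected to lower carbon gain by
concavity — while the early-day fluctuations stay in the linear range. The
canopy response is a stand-in, not plant physiology: it exists so that
saturation, concavity, and diurnal dynamics are present with known ground
truth.

The chamber trajectory is advanced on a 1-s grid with the exact exponential
update (the forcing is piecewise constant at that resolution, so this is
not a discretisation). The CO2 washout rate uses the effective outflow
$F - S\,E$: the outflowing air carries the transpired water, which is
exactly the physics the dilution term of the flux equation corrects for.
Without this the processed fluxes would be biased by roughly
$CO_2 \cdot E$ (~9 % at the defaults) against the generator's own truth.

The multiplexer emits 290-s dwells per chamber in sequence; a matching
dwell (both analyzer cells on buffer air) is inserted whenever 3600 s have
elapsed since the last one. The sampling line relaxes exponentially toward
the newly selected chamber with time constant $t_0/4.6$, so it is ~99 %
purged at the 110-s purge cutoff — one parameter reproducing the
discard-the-first-110-s behaviour. Inter-cell drift is linear in time
(default 0.3 ppm h$^{-1}$) on the sample cell, which makes the hourly
matching correction exactly identifiable by linear interpolation; sensor
noise is independent Gaussian per record (defaults 0.1 ppm CO2, 0.02 mmol
mol$^{-1}$ H2O, 0.01 m s$^{-1}$ flow — typical short-term analyzer noise).
Evapotranspiration truth is proportional to gross assimilation plus a
constant floor; there is no energy balance, as E matters here only through
the dilution term. All randomness is seeded; identical configurations are
bit-reproducible.

Default study conditions: 12 chambers of 0.36 m$^2$ and 19.3 mol at
$F = 0.34$ mol s$^{-1}$, alternating NF/F light treatments, a solstice day
at 46.07° N peaking at 1000 µmol m$^{-2}$ s$^{-1}$, one simulated day at
1 Hz.

## What passing tests do and do not show

The test suite closes the loop end to end: windowed fluxes from a
zero-noise facility day recover the generator's per-chamber source term
within 1 % after settling, the facility-total cumulative carbon closes
within 2 % (trapezoid over window midpoints with linear interpolation
across the ~58-min multiplexing gaps per chamber), and a simulated
scrub-plus-injection campaign regresses measured on reference flux with
slope in [0.99, 1.01] and $R^2 > 0.999$. Individual chambers can deviate
by several percent over a single day because a dwell window occasionally
straddles an hourly light step; this is a property of multiplexed sampling
of a stepped forcing, not of the flux arithmetic, and it averages out at
facility level and over longer runs. None of this validates the simplified
canopy response or the absence of real-world effects — adsorption on
chamber walls, leaks, temperature dependence of photosynthesis, pressure
fluctuations — which the generator deliberately does not model.

Problem sizes in the suite (one simulated day at 1 Hz, 200 noise
replicates for the estimator bias checks, 100 for interval coverage) were
chosen to make Monte-Carlo standard errors comfortably smaller than the
tolerances they check.

## Limitations

* The chamber model is zero-dimensional; $\tau$ absorbs all departures
  from perfect mixing rather than resolving them.
* Only CO2 is mass-balanced; the H2O channel is treated as quasi-steady.
* Matching correction assumes drift varies slowly between hourly events;
  step changes in analyzer behaviour within an hour are not representable.
* The inversion's error model (independent variables, root-sum-square)
  ignores covariance between measured quantities.
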