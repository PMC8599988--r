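---
title: "Reconstructing contact and flight times from effective timings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing contact and flight times from effective timings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grftimes)
```

## The problem

A runner's ground contact time `tc` (foot-strike to toe-off) and
flight time `tf` separate running from walking (duty factor below
50%), track fatigue, and feed estimates of vertical stiffness and
oscillation. Force plates measure them directly with a 20 N threshold,
but a trunk-mounted inertial sensor only sees when the estimated
vertical force crosses *body weight*: it delivers the effective
contact time `tce` (time above `m*g`) and effective flight time `tfe`
(time below). The two pairs conserve step duration,
`tc + tf = tce + tfe`, but are otherwise not interchangeable — how much
of stance sits below body weight depends on the force profile's shape,
which the sensor does not observe.

## Model and procedure

We adopt the classic sine-wave approximation of stance vertical ground
reaction force, `Fz(t) = Fz_max * sin(pi t / tc)`, with the peak fixed
by impulse balance at `Fz_max = m g pi (tf/tc + 1)/2`. The profile is
symmetric about midstance, so a single unknown `tg` — the time from
foot-strike to the first body-weight crossing — links the two timing
systems: `tc = tce + 2 tg`, `tf = tfe - 2 tg`. Imposing
`Fz(tg) = m g` gives a transcendental equation whose residual
(`eq1_residual()`) depends only on ratios of times; its root must be
found numerically.

Four properties shape the implementation:

* **Feasibility.** A root with non-negative flight time exists iff
  `tfe >= r * tce` with `r = 2 asin(2/pi) / (pi - 2 asin(2/pi))
  ≈ 0.7836` (`boundary_ratio_analytic()`); on the boundary the root is
  exactly `tg = tfe/2`, i.e. zero flight. Below the line the sine
  model simply has no physical solution — duty is too high for the
  assumed shape — and the solver reports a value-level `NA`, not an
  error.
* **Bracketing.** The residual falls from `+Inf` at `tg -> 0+`; on the
  physical interval `(0, tfe/2]` we take the residual's minimiser as
  the upper bracket (`stats::optimize()`), declare no solution if the
  minimum is positive, and otherwise run Brent's method
  (`stats::uniroot()`, tolerance 1e-12 s on `tg`, cap 200 iterations,
  lower guard 1e-9 s against the singularity).
* **Scale invariance.** The equation contains only time ratios, so
  `tg(k tce, k tfe) = k tg(tce, tfe)`. We keep the two-variable
  formulation (it is what the downstream polynomial consumes) but the
  invariance is asserted in the tests and explains why `tg` grows
  along the grid diagonal while *decreasing* in `tfe` at fixed `tce`:
  more flight means a higher force peak, so body weight is reached
  sooner.
* **Grid.** The default grid spans 2.5–505 ms per axis at 7.5 ms
  spacing (68 values, 4,624 pairs), wide enough for contact times of
  100–400 ms and flight times of 0–250 ms including atypical runners.
  Axis values are generated from integer indices to keep the count
  immune to floating-point drift. 1,814 pairs fall below the
  feasibility line; the remaining 2,810 carry the `tg` surface.

## Boundary fit

The discrete boundary — the smallest solvable `tfe` per `tce` value,
68 pairs — is fitted with a through-origin least-squares line (a null
`tce` forces a null `tfe`). The slope comes out near 0.795, above the
analytic 0.7836 because each discrete boundary point overshoots the
true line by up to one grid spacing; the overshoot enters the slope
weighted by `tce`, predicting the ≈ 0.011 excess we observe. The fit
uses a random 85% training subset (default split seed 42, recorded in
the object); R² for the no-intercept model is computed against the
zero baseline, the convention consistent with the constraint. With
only 10 held-out points the test RMSE is noisy across splits
(roughly 1.7–4 ms); the slope is extremely stable (range < 0.005)
because the points are nearly collinear.

## Polynomial surrogate

A root search per step is too expensive for firmware, so the solved
surface is compressed into a bivariate polynomial
`P_n(tce, tfe) = sum alpha_ij tce^i tfe^j`, `i + j <= n`, fitted by
ordinary least squares on 85% of the solvable grid points and scored
on the held-out 15%. Numerical choices:

* **Units.** The regression runs in seconds. Monomials up to order 15
  of values ≤ 0.505 stay within a benign dynamic range; in
  milliseconds the columns would span ~40 orders of magnitude.
* **Solver.** Plain monomials are kept as the basis (the model is
  meant to be transcribed into firmware as-is); conditioning is
  handled inside the least-squares solve by scaling every column to
  unit norm and using an SVD pseudo-inverse with the standard
  machine-precision cutoff. A hard error is raised only when there are
  fewer training rows than coefficients. This matters from about
  order 13 up, where an unequilibrated QR loses ~0.1 ms of accuracy.
* **Term order.** Graded lexicographic with `tce` before `tfe`, fixed
  and serialised with the model (`(i, j, value)` triples, schema-1
  JSON, 17 significant digits so a round trip is bitwise).
* **Selection.** Orders 1–15 are scanned on one shared split; the
  smallest order with held-out RMSE < 0.5 ms wins. Because
  `tc = tce + 2 tg`, the contact-time error is exactly twice the `tg`
  error, so the 0.5 ms threshold guarantees better than 1 ms on `tc`.
  On the default grid order 8 is selected (RMSE ≈ 0.4–0.55 ms
  depending on the split); order 3 sits near 2.5 ms and order 14 near
  0.11–0.24 ms, the floor set by the grid resolution and conditioning.
  Held-out errors are mostly below 2 ms, with a couple of points next
  to the feasibility boundary exceeding it — the surface's curvature
  concentrates there.
* **Cost.** With `C = choose(n+2, 2)` terms, evaluation takes
  `C - 3` feature operations plus `C - 1` multiplications and `C - 1`
  additions: 130 operations at order 8, 25 at order 3 — the fallback
  when 2.5 ms accuracy suffices.
* **Prediction guards.** Predictions in the infeasible region error
  (the polynomial is pure extrapolation there); outside the training
  envelope they warn.

A deliberate non-goal: scale invariance means `tg = tce * h(tfe/tce)`
would reduce the problem to one dimension with fewer coefficients.
We keep the two-variable polynomial because that is the form intended
for direct firmware transcription; the reduction is noted as an
extension.

The packaged default model (`default_surrogate()`) is refit by this
package's own pipeline on the default grid rather than transcribed
from published coefficient tables, which are not machine-readable to
full precision; refitting keeps the shipped file consistent with the
code to the last bit.

## Grid resolution

`grid_sensitivity()` rebuilds the grid from 6 x 6 (36 points) up to
202 x 202 (40,804 points) over the same limits and refits each order.
The solved fraction is nearly constant (the feasible region is a fixed
geometric fraction of the square) and the default 68-per-axis grid is
fine enough that the order-8 RMSE sits comfortably below the 0.5 ms
threshold; finer grids mainly lower the high-order floor.

## Validation statistics

`bland_altman()` implements the standard agreement analysis on
`measured - reconstructed` differences: bias, 1.96-SD limits of
agreement, t-quantile confidence intervals (`bias ± t sd/√n` for the
bias, `loa ± t sd √(3/n)` for the limits — the quantile choice is a
documented convention, as is usual when the source analysis does not
state one), RMSE, and Cohen's *d*. The *d* denominator is the pooled
SD of the two measurement series, not the SD of differences; with
typical contact-time data the two conventions differ by nearly a
factor of two, and only the pooled form matches reported effect sizes
of ≈ 1.1 alongside a bias/SD ratio near 2. The relative RMSE uses the
mean measured value as denominator and is informational only.

## Synthetic trials: what they do and do not show

`generate_trial()` builds a single-channel vertical-GRF trace at
1000 Hz from configured per-stride `(tc, tf)` (normal stride-to-stride
variation, SD defaults 10 ms — typical of steady treadmill running at
moderate speed; defaults `tc` = 250 ms, `tf` = 120 ms), with the exact
half-sine stance of the model or a power-skewed variant
`sin(pi t/tc)^q` rescaled to preserve the stance impulse. Ground-truth
events are stored analytically. `filter_and_resample()` applies the
zero-phase fourth-order Butterworth low-pass at 20 Hz and decimates to
200 Hz (the processing that makes plate data resemble an inertial
unit); `detect_events()` applies the 20 N rule for foot-strike/toe-off
and the body-weight rule for the effective events, at sample
resolution with no sub-sample interpolation, inside contiguous
supra-threshold regions.

Two regimes matter:

* **Exact-sine, constant-timing trials** are the model's own world:
  feeding the analytic effective timings to the solver reproduces `tc`
  to 1e-6 s, and the full sampled pipeline (detect at 1000 Hz, predict
  with the order-8 surrogate, reconstruct) recovers `tc` within about
  1 ms plus four sample periods — one millisecond from the surrogate,
  the rest from event quantisation (up to two samples on `tce`)
  propagated through the `tg` surface's sensitivity (gain ≈ 0.7 per
  input, doubled into `tc`). With stride-to-stride variation the
  identity `tfe = tf + 2 tg` itself breaks (an effective flight spans
  two stances with different `tg`), so exactness claims are made only
  for constant timings.
* **Skewed-stance trials** probe the model's central vulnerability:
  a stance with fatter below-body-weight tails than a sine spends more
  of contact under `m g` than the model assumes, so the reconstruction
  systematically *underestimates* `tc` — measured minus reconstructed
  is positive. This reproduces the sign of the bias seen when the sine
  assumption meets real running data; its magnitude on real runners
  (tens of milliseconds) depends on real force-profile shapes that the
  generator does not claim to emulate. Passing synthetic tests
  therefore validates the numerics and the pipeline, not the sine
  assumption itself.

Noise defaults to zero; noisy traces are supported for exploration,
but detection on them is threshold-crossing at sample resolution and
inherits the usual threshold-noise interactions.

## Problem sizes and determinism

The default analyses are small: the full grid solve is a few tenths of
a second, the 1–15 order scan a few seconds, and the test suite runs
the full default grid rather than a down-scaled copy. Every random
choice (train/test splits, synthetic trials) is driven by an explicit
integer seed recorded in the returned object, and refitting with the
same grid and seed reproduces coefficients bitwise.

## Known limitations

* The sine-wave shape is the binding assumption; real vertical GRF has
  impact transients and asymmetry, and reconstructed `tc` inherits
  that model error in full (the surrogate adds < 0.5 ms).
* Near the feasibility boundary the surrogate degrades (errors up to a
  few ms) and the boundary itself is resolved only to one grid
  spacing.
* Event detection is sample-resolution by design; at 200 Hz the
  quantisation term dominates the surrogate error.
* The duty-factor convention (stride = two symmetric steps) is a
  definition, not an estimate; asymmetric gaits violate it.
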