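#' grftimes: contact and flight times from effective timings
#'
#' Sacral inertial sensors measure *effective* contact and flight times
#' (`tce`, `tfe`): the portions of a running step spent above and below
#' body weight. Under the sine-wave model of stance vertical ground
#' reaction force, `Fz(t) = Fz_max * sin(pi * t / tc)`, the true contact
#' time `tc` and flight time `tf` are related to the effective timings by
#' `tc = tce + 2 * tg` and `tf = tfe - 2 * tg`, where `tg` is the time
#' from foot-strike to the first body-weight crossing. `tg` is the root
#' of a transcendental equation and must be found numerically; this
#' package solves it over a grid of `(tce, tfe)` pairs, fits a bivariate
#' polynomial surrogate so the reconstruction can run in constant time,
#' and validates the pipeline on synthetic force traces.
#'
#' All functions work in seconds; user-facing file formats and printed
#' summaries use milliseconds.
#'
#' @name grftimes-package
"_PACKAGE"

#' Peak vertical force of the sine-wave stance model
#'
#' Momentum conservation over one step forces the peak of the half-sine
#' stance profile to `m * g * pi * (tf / tc + 1) / 2`: the impulse of the
#' stance must carry the body through both contact and flight.
#'
#' @param mass body mass (kg).
#' @param tc ground contact time (s), strictly positive.
#' @param tf flight time (s), non-negative.
#' @param g_accel gravitational acceleration (m/s^2).
#' @return Peak vertical force (N). Never less than `m * g * pi / 2`
#'   (the `tf = 0` limit). Depends on `tc`, `tf` only through their
#'   ratio.
#' @examples
#' peak_force(70, 0.25, 0.12)
#' @export
peak_force <- function(mass, tc, tf, g_accel = 9.81) {
  stopifnot(mass > 0, g_accel > 0, tf >= 0)
  if (any(tc <= 0)) {
    stop("`tc` must be strictly positive", call. = FALSE)
  }
  mass * g_accel * pi * (tf / tc + 1) / 2
}

#' Sine-wave vertical ground reaction force during stance
#'
#' @param t time since foot-strike (s), within `[0, tc]`.
#' @param tc ground contact time (s).
#' @param f_max peak vertical force (N), typically from [peak_force()].
#' @return Vertical force `f_max * sin(pi * t / tc)` (N); zero at the
#'   stance edges, `f_max` at midstance.
#' @export
vertical_force <- function(t, tc, f_max) {
  stopifnot(tc > 0)
  if (any(t < 0 | t > tc)) {
    stop("`t` must lie within [0, tc]", call. = FALSE)
  }
  f_max * sin(pi * t / tc)
}

#' Residual of the body-weight crossing equation
#'
#' Writing `tc = tce + 2 * tg` and `tf = tfe - 2 * tg` and requiring the
#' sine-wave force to equal body weight at time `tg` after foot-strike
#' yields
#' `csc(pi * tg / (tce + 2 tg)) = (pi / 2) * ((tfe - 2 tg) / (tce + 2 tg) + 1)`.
#' This function returns left minus right side; its root in `tg` is the
#' model's body-weight crossing time. The equation has no closed-form
#' solution, hence the numerical treatment in [solve_tg()].
#'
#' The residual depends only on time ratios, so it is invariant under a
#' common rescaling of `tg`, `tce`, `tfe`.
#'
#' @param tg candidate crossing time (s), strictly positive.
#' @param tce effective contact time (s).
#' @param tfe effective flight time (s).
#' @return Dimensionless residual; diverges to `+Inf` as `tg -> 0+`.
#' @export
eq1_residual <- function(tg, tce, tfe) {
  stopifnot(tce > 0)
  if (any(tg <= 0)) {
    stop("`tg` must be strictly positive (residual diverges at 0)",
         call. = FALSE)
  }
  angle <- pi * tg / (tce + 2 * tg)
  1 / sin(angle) - (pi / 2) * ((tfe - 2 * tg) / (tce + 2 * tg) + 1)
}

#' Analytic feasibility ratio of the sine-wave model
#'
#' Setting `tf = 0` in the crossing equation and solving analytically
#' gives the smallest `tfe / tce` ratio for which a root with
#' non-negative flight time exists: `2 * theta / (pi - 2 * theta)` with
#' `theta = asin(2 / pi)`, about 0.7836. Below `tfe = ratio * tce` the
#' model admits no physical solution; exactly on it the root is
#' `tg = tfe / 2` (zero flight time).
#'
#' The boundary slope fitted on a discrete grid ([fit_boundary()])
#' slightly exceeds this ratio because grid boundary points overshoot
#' the true line by up to one grid spacing.
#'
#' @return The dimensionless ratio, about 0.78360.
#' @export
boundary_ratio_analytic <- function() {
  theta <- asin(2 / pi)
  2 * theta / (pi - 2 * theta)
}

#' Reconstruct full stride timings from effective timings and tg
#'
#' @param tce,tfe effective contact and flight times (s).
#' @param tg body-weight crossing time (s), non-negative; typically from
#'   [solve_tg()] or [predict.tg_surrogate()].
#' @return A data frame with columns `tc`, `tf`, `tce`, `tfe`, `tg`
#'   (all s). Satisfies `tc = tce + 2 tg`, `tf = tfe - 2 tg`, and step
#'   duration conservation `tc + tf = tce + tfe` exactly.
#' @export
reconstruct_from_tg <- function(tce, tfe, tg) {
  stopifnot(tce > 0, tfe > 0)
  if (any(tg < 0)) {
    stop("`tg` must be non-negative", call. = FALSE)
  }
  if (any(tfe - 2 * tg < 0)) {
    stop("infeasible reconstruction: tfe - 2 * tg < 0 (negative flight time)",
         call. = FALSE)
  }
  tc <- tce + 2 * tg
  # tf as the step-duration remainder keeps tc + tf = tce + tfe exact
  data.frame(tc = tc, tf = (tce + tfe) - tc,
             tce = tce, tfe = tfe, tg = tg)
}

#' Percentage of contact time spent below body weight
#'
#' @param tce effective contact time (s).
#' @param tg body-weight crossing time (s).
#' @return `100 * 2 * tg / (tce + 2 * tg)`, a percentage in `[0, 100)`,
#'   increasing in `tg`.
#' @export
under_bw_fraction <- function(tce, tg) {
  stopifnot(tce > 0, tg >= 0)
  100 * 2 * tg / (tce + 2 * tg)
}

#' Running duty factor
#'
#' Fraction of the stride spent in ground contact, with stride duration
#' taken as `2 * (tc + tf)` (two symmetric steps). Under this convention
#' the duty factor is below 0.5 for any positive flight time and exactly
#' 0.5 at `tf = 0`, matching the usual running/walking divide.
#'
#' @param tc ground contact time (s), strictly positive.
#' @param tf flight time (s), non-negative.
#' @return Dimensionless duty factor in `(0, 0.5]`.
#' @export
duty_factor <- function(tc, tf) {
  stopifnot(tc > 0, tf >= 0)
  tc / (2 * (tc + tf))
}
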