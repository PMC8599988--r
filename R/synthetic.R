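#' Configuration for a synthetic force-plate trial
#'
#' Describes a treadmill-like running trial for the generator: a
#' sequence of stances separated by aerial phases, sampled as a single
#' vertical-force channel at 1000 Hz. Per-stride contact and flight
#' times are drawn from normal distributions (SD 0 gives fixed
#' timings). The stance shape is either the exact half-sine of the
#' reconstruction model or a power-skewed sine `sin(pi t / tc)^skew`
#' rescaled to preserve the stance impulse — a shape with fatter
#' below-body-weight tails, used to probe the bias the sine assumption
#' introduces on non-sine gaits.
#'
#' @param n_strides number of stances.
#' @param tc,tf mean contact and flight times (s); defaults typical of
#'   treadmill running at moderate speed.
#' @param tc_sd,tf_sd stride-to-stride SDs (s).
#' @param shape `"sine"` or `"skewed"`.
#' @param skew skew exponent `q >= 1` for the skewed shape (1 = sine).
#' @param mass body mass (kg).
#' @param g_accel gravitational acceleration (m/s^2).
#' @param noise_sd additive Gaussian noise on the sampled force (N).
#' @param rate sampling rate (Hz).
#' @param seed integer seed; the whole trial is reproducible from it.
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_strides = 20L, tc = 0.25, tf = 0.12,
                         tc_sd = 0.01, tf_sd = 0.01,
                         shape = c("sine", "skewed"), skew = 1.5,
                         mass = 70, g_accel = 9.81, noise_sd = 0,
                         rate = 1000, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n_strides >= 1, tc > 0, tf >= 0, tc_sd >= 0, tf_sd >= 0,
            skew >= 1, mass > 0, g_accel > 0, noise_sd >= 0, rate > 0)
  structure(list(n_strides = as.integer(n_strides), tc = tc, tf = tf,
                 tc_sd = tc_sd, tf_sd = tf_sd, shape = shape, skew = skew,
                 mass = mass, g_accel = g_accel, noise_sd = noise_sd,
                 rate = rate, seed = as.integer(seed)),
            class = "trial_config")
}

# Impulse-preserving peak for the shape sin(pi t / tc)^q: the mean of
# sin^q over the stance is Gamma((q+1)/2) / (sqrt(pi) Gamma(q/2 + 1)),
# so the peak scales the sine-model peak by (2/pi) / that mean.
skewed_peak <- function(mass, g_accel, tc, tf, q) {
  mean_shape <- gamma((q + 1) / 2) / (sqrt(pi) * gamma(q / 2 + 1))
  mass * g_accel * (tf / tc + 1) / mean_shape
}

#' Generate a synthetic vertical-GRF trial
#'
#' Samples the configured stance/flight sequence at `rate` Hz (sample
#' `k` sits at time `k / rate`, 0-based; force is exactly zero in
#' flight before any noise) and records the analytic ground truth per
#' stance: foot-strike `fs`, toe-off `to`, and the body-weight
#' crossings `efs`/`eto` obtained by inverting the stance shape at
#' `F = m g`. For sine stances `efs = fs + (tc / pi) * asin(mg / Fmax)`;
#' the skewed shape inverts `sin^q`. Stances whose peak stays below
#' body weight carry `NA` crossings.
#'
#' @param config a [trial_config()].
#' @return An object of class `force_trace`: `time` (s), `fz` (N),
#'   `rate`, `mass`, `g_accel`, and `truth` (data frame with per-stance
#'   `fs`, `efs`, `eto`, `to`, `tc`, `tf`, `tg`; last stance has `NA`
#'   flight).
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  with_seed(config$seed, {
    tc_k <- pmax(stats::rnorm(config$n_strides, config$tc, config$tc_sd),
                 0.05)
    tf_k <- pmax(stats::rnorm(config$n_strides, config$tf, config$tf_sd),
                 0.01)
    mg <- config$mass * config$g_accel
    fs <- cumsum(c(0.1, (tc_k + tf_k)[-config$n_strides]))
    to <- fs + tc_k
    peak <- if (config$shape == "sine") {
      peak_force(config$mass, tc_k, tf_k, config$g_accel)
    } else {
      skewed_peak(config$mass, config$g_accel, tc_k, tf_k, config$skew)
    }
    q <- if (config$shape == "sine") 1 else config$skew
    tg_k <- ifelse(peak > mg,
                   (tc_k / pi) * asin(pmin((mg / peak)^(1 / q), 1)),
                   NA_real_)
    total <- fs[config$n_strides] + tc_k[config$n_strides] + 0.1
    time <- seq(0, total, by = 1 / config$rate)
    fz <- numeric(length(time))
    for (k in seq_len(config$n_strides)) {
      in_stance <- time >= fs[k] & time <= to[k]
      # clamp: sin can round to a tiny negative at the stance edges,
      # which a non-integer exponent would turn into NaN
      fz[in_stance] <- peak[k] *
        pmax(sin(pi * (time[in_stance] - fs[k]) / tc_k[k]), 0)^q
    }
    if (config$noise_sd > 0) {
      fz <- fz + stats::rnorm(length(fz), 0, config$noise_sd)
    }
    truth <- data.frame(fs = fs, efs = fs + tg_k, eto = to - tg_k, to = to,
                        tc = tc_k, tf = c(tf_k[-config$n_strides], NA),
                        tg = tg_k)
    structure(list(time = time, fz = fz, rate = config$rate,
                   mass = config$mass, g_accel = config$g_accel,
                   truth = truth, config = config),
              class = "force_trace")
  })
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("Vertical-GRF trace: %d samples at %g Hz (%.2f s), mass %g kg\n",
              length(x$fz), x$rate, max(x$time), x$mass))
  if (!is.null(x$truth)) {
    cat(sprintf("  %d ground-truth stances\n", nrow(x$truth)))
  }
  invisible(x)
}

#' Low-pass filter and downsample a force trace
#'
#' Fourth-order Butterworth low-pass at 20 Hz applied forward and
#' backward ([signal::filtfilt()], zero phase so event timings do not
#' lag), then decimation to the output rate — the processing used to
#' make force-plate data resemble what a trunk inertial unit delivers.
#'
#' @param trace a `force_trace`.
#' @param cutoff low-pass cutoff (Hz); must respect the output Nyquist.
#' @param order Butterworth order.
#' @param out_rate output sampling rate (Hz); must divide the input
#'   rate.
#' @return A `force_trace` at `out_rate`, ground truth carried over.
#' @export
filter_and_resample <- function(trace, cutoff = 20, order = 4,
                                out_rate = 200) {
  stopifnot(inherits(trace, "force_trace"), cutoff > 0, order >= 1)
  if (cutoff >= out_rate / 2) {
    stop("`cutoff` must be below the output Nyquist rate", call. = FALSE)
  }
  factor <- trace$rate / out_rate
  if (abs(factor - round(factor)) > 1e-9) {
    stop(sprintf("output rate %g Hz does not divide input rate %g Hz",
                 out_rate, trace$rate), call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (trace$rate / 2), type = "low")
  fz <- signal::filtfilt(bf, trace$fz)
  keep <- seq(1, length(fz), by = round(factor))
  out <- trace
  out$time <- trace$time[keep]
  out$fz <- fz[keep]
  out$rate <- out_rate
  out
}

#' Detect gait events from a force trace by thresholding
#'
#' Segments the trace into running steps as contiguous runs of samples
#' at or above the step threshold (20 N, the force-plate convention),
#' then within each step takes foot-strike `fs` and toe-off `to` as the
#' first and last supra-threshold samples, and the effective events
#' `efs`/`eto` as the first and last samples at or above body weight
#' `m g`. Events are reported at sample timestamps — no sub-sample
#' interpolation, matching "first data point greater or equal" rules.
#' Steps whose peak never reaches body weight get `NA` effective
#' events.
#'
#' @param trace a `force_trace`.
#' @param step_threshold contact threshold (N).
#' @return An object of class `event_set`: data frame with per-step
#'   `fs`, `efs`, `eto`, `to` (s), carrying `rate`, ordered
#'   `fs <= efs <= eto <= to` on every detected step.
#' @export
detect_events <- function(trace, step_threshold = 20) {
  stopifnot(inherits(trace, "force_trace"))
  mg <- trace$mass * trace$g_accel
  on <- trace$fz >= step_threshold
  if (!any(on)) {
    out <- data.frame(fs = numeric(0), efs = numeric(0),
                      eto = numeric(0), to = numeric(0))
  } else {
    r <- rle(on)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- cbind(starts[r$values], ends[r$values])
    out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(k) {
      idx <- runs[k, 1]:runs[k, 2]
      above <- idx[trace$fz[idx] >= mg]
      data.frame(fs = trace$time[runs[k, 1]],
                 efs = if (length(above)) trace$time[min(above)] else NA,
                 eto = if (length(above)) trace$time[max(above)] else NA,
                 to = trace$time[runs[k, 2]])
    }))
  }
  structure(out, class = c("event_set", "data.frame"), rate = trace$rate)
}

#' Step timings from detected gait events
#'
#' Converts per-step events into durations: `tc = to - fs` and
#' `tce = eto - efs` within a step; `tf` and `tfe` bridge to the next
#' step (`fs[k+1] - to[k]`, `efs[k+1] - eto[k]`), so the last step has
#' `NA` flight entries. Step duration conservation
#' `tc + tf = tce + tfe` holds to within two sample periods.
#'
#' @param events an `event_set` from [detect_events()].
#' @return Data frame with per-step `tc`, `tf`, `tce`, `tfe` (s).
#' @export
timings_from_events <- function(events) {
  stopifnot(inherits(events, "event_set"))
  n <- nrow(events)
  if (n == 0) {
    return(data.frame(tc = numeric(0), tf = numeric(0),
                      tce = numeric(0), tfe = numeric(0)))
  }
  with_ok <- stats::complete.cases(events[, c("fs", "efs", "eto", "to")])
  bad_order <- with_ok & !(events$fs <= events$efs &
                             events$efs <= events$eto &
                             events$eto <= events$to)
  if (any(bad_order)) {
    stop("event ordering violated (expected fs <= efs <= eto <= to)",
         call. = FALSE)
  }
  data.frame(tc = events$to - events$fs,
             tf = c(events$fs[-1] - events$to[-n], NA),
             tce = events$eto - events$efs,
             tfe = c(events$efs[-1] - events$eto[-n], NA))
}
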