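test_that("sine trials carry exact analytic ground truth", {
  cfg <- trial_config(n_strides = 5, tc = 0.25, tf = 0.12,
                      tc_sd = 0, tf_sd = 0, noise_sd = 0, seed = 3)
  tr <- generate_trial(cfg)
  mg <- 70 * 9.81
  f_max <- peak_force(70, 0.25, 0.12)
  expect_equal(tr$truth$efs - tr$truth$fs,
               rep((0.25 / pi) * asin(mg / f_max), 5), tolerance = 1e-12)
  # sampled force matches the analytic sine at sample times
  k <- which(tr$time >= tr$truth$fs[2] & tr$time <= tr$truth$to[2])
  expect_equal(tr$fz[k],
               f_max * sin(pi * (tr$time[k] - tr$truth$fs[2]) / 0.25),
               tolerance = 1e-9)
  # force is identically zero in flight
  aloft <- tr$time > tr$truth$to[2] & tr$time < tr$truth$fs[3]
  expect_true(all(tr$fz[aloft] == 0))
})

test_that("trials are reproducible from their seed", {
  cfg <- trial_config(n_strides = 8, noise_sd = 5, seed = 21)
  a <- generate_trial(cfg)
  b <- generate_trial(cfg)
  expect_identical(a$fz, b$fz)
  c <- generate_trial(trial_config(n_strides = 8, noise_sd = 5, seed = 22))
  expect_false(identical(a$fz, c$fz))
})

test_that("filtering keeps DC, crushes 50 Hz, and decimates five-fold", {
  flat <- structure(list(time = (0:2999) / 1000,
                         fz = rep(700, 3000), rate = 1000,
                         mass = 70, g_accel = 9.81, truth = NULL),
                    class = "force_trace")
  out <- filter_and_resample(flat)
  expect_equal(out$rate, 200)
  expect_equal(length(out$fz), 600)
  expect_equal(out$fz[100:500], rep(700, 401), tolerance = 1e-6)

  wave <- flat
  wave$fz <- sin(2 * pi * 50 * wave$time)
  filtered <- filter_and_resample(wave)
  mid <- filtered$fz[100:500]
  expect_lt(max(abs(mid)), 0.05)

  expect_error(filter_and_resample(flat, out_rate = 300), "divide")
  expect_error(filter_and_resample(flat, cutoff = 150), "Nyquist")
})

test_that("threshold detection lands within one sample of the analytic crossings", {
  cfg <- trial_config(n_strides = 6, tc = 0.25, tf = 0.12,
                      tc_sd = 0, tf_sd = 0, noise_sd = 0, seed = 4)
  tr <- generate_trial(cfg)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 6)
  expect_true(all(ev$fs <= ev$efs & ev$efs <= ev$eto & ev$eto <= ev$to))
  dt <- 1 / tr$rate
  # effective events against the analytic body-weight crossings
  expect_lt(max(abs(ev$efs - tr$truth$efs)), dt + 1e-12)
  expect_lt(max(abs(ev$eto - tr$truth$eto)), dt + 1e-12)
  # 20 N events against the analytic 20 N crossings
  f_max <- peak_force(70, 0.25, 0.12)
  t20 <- (0.25 / pi) * asin(20 / f_max)
  expect_lt(max(abs(ev$fs - (tr$truth$fs + t20))), dt + 1e-12)
  expect_lt(max(abs(ev$to - (tr$truth$to - t20))), dt + 1e-12)
})

test_that("timings from events: resolution, conservation, edge cases", {
  cfg <- trial_config(n_strides = 6, tc = 0.26, tf = 0.11,
                      tc_sd = 0, tf_sd = 0, noise_sd = 0, seed = 9)
  tr <- generate_trial(cfg)
  tm <- timings_from_events(detect_events(tr))
  dt <- 1 / tr$rate
  tg_true <- tr$truth$tg[1]
  expect_lt(max(abs(tm$tce - (0.26 - 2 * tg_true))), 2 * dt)
  full <- !is.na(tm$tf)
  expect_lt(max(abs((tm$tc + tm$tf - tm$tce - tm$tfe)[full])), 2 * dt)
  expect_true(is.na(tm$tf[6]) && is.na(tm$tfe[6]))

  silent <- structure(list(time = (0:99) / 1000, fz = rep(0, 100),
                           rate = 1000, mass = 70, g_accel = 9.81,
                           truth = NULL), class = "force_trace")
  expect_equal(nrow(detect_events(silent)), 0)
  expect_equal(nrow(timings_from_events(detect_events(silent))), 0)
})

test_that("round trip: detect, predict, reconstruct recovers true contact time", {
  # constant-timing trials: the model identity tfe = tf + 2 tg requires
  # equal tg in consecutive stances
  cfg <- trial_config(n_strides = 10, tc = 0.25, tf = 0.12,
                      tc_sd = 0, tf_sd = 0, noise_sd = 0, seed = 14)
  tr <- generate_trial(cfg)
  tm <- timings_from_events(detect_events(tr))
  full <- !is.na(tm$tfe)
  model <- default_surrogate()
  out <- reconstruct_dataset(model, data.frame(tce = tm$tce[full],
                                               tfe = tm$tfe[full]))
  expect_equal(nrow(out), sum(full))
  err <- out$tc - tr$truth$tc[full]
  # 1 ms surrogate budget on tc, plus sampling: events quantise tce by
  # up to 2 samples and the tg surface responds to the tce/tfe shifts
  # with gain near 0.7 each, doubled into tc — about 4 sample periods
  expect_lt(max(abs(err)), 1e-3 + 4 / tr$rate)
})

test_that("round trip through the direct solver on analytic timings is near exact", {
  cfg <- trial_config(n_strides = 8, tc = 0.27, tf = 0.10,
                      tc_sd = 0, tf_sd = 0, noise_sd = 0, seed = 6)
  tr <- generate_trial(cfg)
  truth <- tr$truth
  n <- nrow(truth)
  k <- seq_len(n - 1)                       # steps with a following stance
  tce <- truth$eto[k] - truth$efs[k]
  tfe <- truth$efs[k + 1] - truth$eto[k]
  tg_hat <- solve_tg(tce, tfe)
  tc_hat <- tce + 2 * tg_hat
  expect_lt(max(abs(tc_hat - truth$tc[k])), 1e-6)
})

test_that("skewed stances bias the reconstruction the expected way", {
  cfg <- trial_config(n_strides = 12, tc = 0.25, tf = 0.12,
                      tc_sd = 0, tf_sd = 0, shape = "skewed", skew = 1.5,
                      noise_sd = 0, seed = 5)
  tr <- generate_trial(cfg)
  tm <- timings_from_events(detect_events(tr))
  full <- !is.na(tm$tfe)
  out <- reconstruct_dataset(default_surrogate(),
                             data.frame(tce = tm$tce[full],
                                        tfe = tm$tfe[full]))
  bias <- mean(tr$truth$tc[full] - out$tc)
  expect_gt(bias, 0)           # measured tc exceeds reconstructed tc
  expect_gt(bias, 2 / tr$rate) # clearly beyond sampling error
})

test_that("skewed stance preserves the step impulse", {
  q <- 1.7
  tc <- 0.24; tf <- 0.13; mass <- 70
  peak <- grftimes:::skewed_peak(mass, 9.81, tc, tf, q)
  imp <- integrate(function(t) peak * sin(pi * t / tc)^q, 0, tc,
                   rel.tol = 1e-10)$value
  expect_equal(imp, mass * 9.81 * (tc + tf), tolerance = 1e-6)
})
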