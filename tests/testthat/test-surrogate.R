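test_that("monomial features have C(n+2, 2) terms in graded lex order", {
  expect_equal(ncol(polynomial_features(0.2, 0.2, 1)), 3)
  expect_equal(ncol(polynomial_features(0.2, 0.2, 3)), 10)
  expect_equal(ncol(polynomial_features(0.2, 0.2, 8)), 45)
  X <- polynomial_features(c(0.2, 0.3), c(0.25, 0.35), 2)
  expect_identical(colnames(X)[1:6],
                   c("tce^0.tfe^0", "tce^1.tfe^0", "tce^0.tfe^1",
                     "tce^2.tfe^0", "tce^1.tfe^1", "tce^0.tfe^2"))
  expect_equal(X[, "tce^1.tfe^1"], c(0.2 * 0.25, 0.3 * 0.35))
  expect_error(polynomial_features(0.2, 0.2, 0), "order")
})

test_that("fit recovers an exactly polynomial surface to machine precision", {
  grid <- default_grid
  # overwrite tg with a known order-2 polynomial of the timings
  p <- grid$points
  grid$points$tg <- 1e-3 + 0.1 * p$tce - 0.05 * p$tfe +
    0.2 * p$tce^2 - 0.3 * p$tce * p$tfe + 0.15 * p$tfe^2
  fit <- fit_tg_surrogate(grid, order = 2)
  expect_lt(fit$rmse, 1e-12)
  expect_equal(unname(fit$alpha),
               c(1e-3, 0.1, -0.05, 0.2, -0.3, 0.15), tolerance = 1e-9)
})

test_that("surrogate fitting is deterministic given grid and seed", {
  a <- fit_tg_surrogate(default_grid, order = 5, seed = 11)
  b <- fit_tg_surrogate(default_grid, order = 5, seed = 11)
  expect_identical(a$alpha, b$alpha)
  c <- fit_tg_surrogate(default_grid, order = 5, seed = 12)
  expect_false(identical(a$alpha, c$alpha))
})

test_that("order-8 surrogate tracks the numerical solver closely", {
  fit <- fit_tg_surrogate(default_grid, order = 8)
  solved <- default_grid$points[!is.na(default_grid$points$tg), ]
  test_rows <- solved[fit$test_idx, ]
  expect_lt(fit$rmse, 0.6e-3)
  pred <- predict(fit, test_rows[, c("tce", "tfe")])
  err <- abs(pred - test_rows$tg)
  # differences are mostly below 2 ms; only a couple of held-out points
  # right next to the feasibility boundary exceed it
  expect_lte(sum(err > 2e-3), 5)
  expect_lt(max(err), 1e-2)
  expect_lt(stats::median(err), 0.5e-3)
  # spot check against the solver: within 1 ms at the reference pair
  expect_lt(abs(predict(fit, data.frame(tce = 0.2, tfe = 0.2)) -
                  solve_tg(0.2, 0.2)), 1e-3)
})

test_that("reconstructed-tc error is exactly twice the tg error", {
  fit <- fit_tg_surrogate(default_grid, order = 8)
  solved <- default_grid$points[!is.na(default_grid$points$tg), ]
  test_rows <- solved[fit$test_idx, ]
  tg_pred <- predict(fit, test_rows[, c("tce", "tfe")])
  err_tg <- tg_pred - test_rows$tg
  tc_pred <- test_rows$tce + 2 * tg_pred
  tc_true <- test_rows$tce + 2 * test_rows$tg
  err_tc <- tc_pred - tc_true
  expect_equal(sqrt(mean(err_tc^2)), 2 * sqrt(mean(err_tg^2)),
               tolerance = 1e-12)
})

test_that("prediction guards the infeasible region and training envelope", {
  fit <- fit_tg_surrogate(default_grid, order = 8)
  expect_error(predict(fit, data.frame(tce = 0.2, tfe = 0.1)), "infeasible")
  expect_warning(predict(fit, data.frame(tce = 0.6, tfe = 0.7)), "envelope")
  # zero and constant polynomials evaluate trivially
  z <- fit
  z$alpha[] <- 0
  expect_equal(predict(z, data.frame(tce = 0.2, tfe = 0.2)), 0)
  z$alpha[1] <- 0.01
  expect_equal(predict(z, data.frame(tce = c(0.2, 0.3),
                                     tfe = c(0.2, 0.3))), c(0.01, 0.01))
})

test_that("fitting more coefficients than training points is an error", {
  tiny <- solve_grid(grid_spec(0.0025, 0.505, (0.505 - 0.0025) / 5))
  expect_error(fit_tg_surrogate(tiny, order = 8), "rank-deficient")
})

test_that("order scan selects the smallest adequate order", {
  scan <- order_scan(default_grid, orders = 1:3, threshold = Inf)
  expect_equal(scan$selected_order, 1L)
  expect_error(order_scan(default_grid, orders = 1:2, threshold = 1e-6),
               "no order")
})

test_that("operation counts follow 3 * C(n+2,2) - 5", {
  expect_equal(operation_count(8)$total, 130)
  expect_equal(operation_count(3)$total, 25)
  expect_equal(operation_count(1)$total, 4)
  oc <- operation_count(8)
  expect_equal(oc$features + oc$multiplications + oc$additions, oc$total)
})

test_that("coarser grids still build, solve, and fit", {
  sens <- grid_sensitivity(axis_sizes = c(6, 20), orders = c(1, 3))
  expect_equal(nrow(sens), 4)
  expect_equal(unique(sens$n_total), c(36, 400))
  expect_true(all(sens$rmse > 0))
  # solved fraction is roughly the geometric fraction above the boundary
  frac <- unique(sens$n_solved / sens$n_total)
  expect_lt(diff(range(frac)), 0.15)
})

test_that("model JSON round trip reproduces predictions bitwise", {
  fit <- fit_tg_surrogate(default_grid, order = 8)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_model(fit, path)
  back <- load_model(path)
  pairs <- random_feasible_pairs(100)
  keep <- pairs$tfe <= 0.505 & pairs$tce <= 0.505
  pairs <- pairs[keep, ]
  expect_identical(predict(fit, pairs), predict(back, pairs))
})
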