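#' Bivariate monomial features of effective timings
#'
#' Builds the design matrix of all monomials `tce^i * tfe^j` with
#' `0 <= i + j <= order`, in graded lexicographic order with `tce`
#' before `tfe`: degree 0 first, then within each total degree `d` the
#' exponent `i` of `tce` descends from `d` to 0. The term order is fixed
#' so serialised models are portable.
#'
#' @param tce,tfe effective timings (s), equal-length vectors.
#' @param order polynomial order `n >= 1`.
#' @return Matrix with `choose(order + 2, 2)` columns named
#'   `tce^i.tfe^j`; attribute `exponents` holds the `(i, j)` pairs.
#' @examples
#' ncol(polynomial_features(0.2, 0.2, 8))  # 45 terms
#' @export
polynomial_features <- function(tce, tfe, order) {
  if (length(order) != 1 || order < 1 || order != round(order)) {
    stop("`order` must be an integer >= 1", call. = FALSE)
  }
  exps <- surrogate_exponents(order)
  X <- mapply(function(i, j) tce^i * tfe^j, exps$i, exps$j)
  X <- matrix(X, nrow = length(tce), ncol = nrow(exps))
  colnames(X) <- sprintf("tce^%d.tfe^%d", exps$i, exps$j)
  attr(X, "exponents") <- exps
  X
}

# (i, j) exponent pairs in graded lex order, tce before tfe.
surrogate_exponents <- function(order) {
  out <- do.call(rbind, lapply(0:order, function(d) {
    data.frame(i = d:0, j = 0:d)
  }))
  rownames(out) <- NULL
  out
}

#' Fit a polynomial surrogate of the tg surface
#'
#' Ordinary least squares fit of a bivariate polynomial
#' `P_n(tce, tfe) = sum alpha_ij tce^i tfe^j` (intercept and all
#' interaction terms, `i + j <= n`) to the numerically solved `tg`
#' values of a grid, using a random 85% of the solvable points for
#' training and the held-out 15% for the reported RMSE and R^2. Times
#' enter the regression in seconds — monomials of order up to 15 stay
#' within a tame dynamic range there — and no basis change is applied;
#' numerical stability is handled inside the least-squares solve
#' (column-equilibrated singular value decomposition).
#'
#' The surrogate replaces the per-pair root search with a fixed, cheap
#' polynomial evaluation, the form a sports-watch algorithm can run in
#' real time.
#'
#' @param grid a solved `tg_grid` (see [solve_grid()]).
#' @param order polynomial order, default 8 (the smallest order whose
#'   held-out RMSE drops below 0.5 ms on the default grid).
#' @param train_fraction training fraction of the solvable points.
#' @param seed integer seed for the train/test split.
#' @return An object of class `tg_surrogate`: coefficients `alpha`
#'   (named vector, graded lex order), `exponents`, `order`, `units`
#'   (`"s"`), `rmse` and `r_squared` (held-out), split bookkeeping, and
#'   the training grid's spec.
#' @export
fit_tg_surrogate <- function(grid, order = 8L, train_fraction = 0.85,
                             seed = 42L) {
  stopifnot(inherits(grid, "tg_grid"))
  solved <- grid$points[!is.na(grid$points$tg), ]
  n <- nrow(solved)
  if (n < 2) stop("grid has too few solved points to fit", call. = FALSE)
  n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
  train_idx <- sort(with_seed(seed, sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)
  X <- polynomial_features(solved$tce, solved$tfe, order)
  alpha <- lstsq(X[train_idx, , drop = FALSE], solved$tg[train_idx],
                 context = sprintf("order-%d surrogate fit on %d points",
                                   order, n_train))
  names(alpha) <- colnames(X)
  pred <- drop(X[test_idx, , drop = FALSE] %*% alpha)
  res <- solved$tg[test_idx] - pred
  structure(list(alpha = alpha,
                 exponents = attr(X, "exponents"),
                 order = as.integer(order), units = "s",
                 rmse = sqrt(mean(res^2)),
                 r_squared = 1 - sum(res^2) /
                   sum((solved$tg[test_idx] - mean(solved$tg[test_idx]))^2),
                 n_points = n, n_train = n_train,
                 train_idx = train_idx, test_idx = test_idx,
                 train_fraction = train_fraction, seed = seed,
                 spec = grid$spec,
                 envelope = list(min = min(grid$axis), max = max(grid$axis))),
            class = "tg_surrogate")
}

#' @export
print.tg_surrogate <- function(x, ...) {
  cat(sprintf("Polynomial tg surrogate, order %d (%d terms)\n",
              x$order, length(x$alpha)))
  cat(sprintf("  held-out RMSE %.3f ms,  R^2 %.2f%%  (%d solvable points, %d trained)\n",
              x$rmse * 1000, x$r_squared * 100, x$n_points, x$n_train))
  invisible(x)
}

#' @export
summary.tg_surrogate <- function(object, ...) {
  ops <- operation_count(object$order)
  cat(sprintf("Bivariate polynomial surrogate of the tg surface (units: %s)\n",
              object$units))
  print(object)
  cat(sprintf("  evaluation cost: %d operations (%d features + %d mult + %d add)\n",
              ops$total, ops$features, ops$multiplications, ops$additions))
  cat(sprintf("  split seed %d, train fraction %.2f\n",
              object$seed, object$train_fraction))
  invisible(object)
}

#' @export
coef.tg_surrogate <- function(object, ...) object$alpha

#' Predict tg from effective timings with the surrogate
#'
#' Evaluates the fitted polynomial at new `(tce, tfe)` pairs. Pairs in
#' the infeasible region (`tfe` below the analytic feasibility line,
#' where the model has no solution and the polynomial is pure
#' extrapolation) raise an error; pairs outside the training envelope
#' are flagged with a warning.
#'
#' @param object a `tg_surrogate`.
#' @param newdata data frame with columns `tce`, `tfe` (s).
#' @param ... unused.
#' @return Predicted `tg` (s).
#' @export
predict.tg_surrogate <- function(object, newdata, ...) {
  stopifnot(is.data.frame(newdata),
            all(c("tce", "tfe") %in% names(newdata)))
  bad <- newdata$tfe < boundary_ratio_analytic() * newdata$tce
  if (any(bad)) {
    stop(sprintf("%d pair(s) lie in the infeasible region tfe < %.4f tce; the surrogate is meaningless there",
                 sum(bad), boundary_ratio_analytic()), call. = FALSE)
  }
  outside <- newdata$tce < object$envelope$min |
    newdata$tce > object$envelope$max |
    newdata$tfe < object$envelope$min |
    newdata$tfe > object$envelope$max
  if (any(outside)) {
    warning(sprintf("%d pair(s) outside the training envelope [%g, %g] s; prediction is extrapolation",
                    sum(outside), object$envelope$min, object$envelope$max),
            call. = FALSE)
  }
  X <- polynomial_features(newdata$tce, newdata$tfe, object$order)
  drop(X %*% object$alpha)
}

#' Scan polynomial orders and select the cheapest adequate surrogate
#'
#' Fits surrogates of each order on a single shared train/test split
#' and records the held-out RMSE and R^2. The selected order is the
#' smallest whose RMSE falls below the threshold; 0.5 ms on `tg`
#' guarantees better than 1 ms on the reconstructed contact time
#' (`tc = tce + 2 tg` doubles the error). On the default grid the
#' selected order is 8.
#'
#' @param grid a solved `tg_grid`.
#' @param orders integer vector of orders to scan.
#' @param threshold RMSE selection threshold (s); default 0.5 ms.
#' @param train_fraction,seed split settings shared across orders.
#' @return An object of class `order_scan`: data frame `results`
#'   (`order`, `rmse`, `r_squared`), `selected_order`, `threshold`.
#' @export
order_scan <- function(grid, orders = 1:15, threshold = 0.5e-3,
                       train_fraction = 0.85, seed = 42L) {
  stopifnot(length(orders) >= 1, threshold > 0)
  fits <- lapply(orders, function(n) {
    fit_tg_surrogate(grid, order = n, train_fraction = train_fraction,
                     seed = seed)
  })
  results <- data.frame(order = as.integer(orders),
                        rmse = vapply(fits, `[[`, numeric(1), "rmse"),
                        r_squared = vapply(fits, `[[`, numeric(1),
                                           "r_squared"))
  ok <- results$order[results$rmse < threshold]
  if (length(ok) == 0) {
    stop(sprintf("no order in %d..%d reaches RMSE < %.3f ms (best: %.3f ms)",
                 min(orders), max(orders), threshold * 1000,
                 min(results$rmse) * 1000), call. = FALSE)
  }
  structure(list(results = results, selected_order = min(ok),
                 threshold = threshold, seed = seed,
                 fits = stats::setNames(fits, orders)),
            class = "order_scan")
}

#' @export
print.order_scan <- function(x, ...) {
  df <- x$results
  cat(sprintf("Order scan %d..%d, threshold %.2f ms on held-out tg RMSE\n",
              min(df$order), max(df$order), x$threshold * 1000))
  out <- data.frame(order = df$order,
                    rmse_ms = round(df$rmse * 1000, 3),
                    r_squared = round(df$r_squared, 5))
  print(out, row.names = FALSE)
  cat(sprintf("Selected order: %d\n", x$selected_order))
  invisible(x)
}

#' Arithmetic cost of evaluating an order-n bivariate polynomial
#'
#' With `C = choose(n + 2, 2)` terms: `C - 3` operations to build the
#' monomial features beyond `1, tce, tfe`, then `C - 1` multiplications
#' and `C - 1` additions to accumulate the polynomial — `3 C - 5` in
#' total (sequential evaluation). Order 8 costs 130 operations; falling
#' back to order 3 costs 25, a five-fold speedup for firmware with
#' tight budgets.
#'
#' @param order polynomial order `n >= 1`; vectorised.
#' @return Data frame with columns `order`, `terms`, `features`,
#'   `multiplications`, `additions`, `total`.
#' @export
operation_count <- function(order) {
  stopifnot(order >= 1, order == round(order))
  C <- choose(order + 2, 2)
  data.frame(order = as.integer(order), terms = C, features = C - 3,
             multiplications = C - 1, additions = C - 1, total = 3 * C - 5)
}

#' Surrogate accuracy as a function of grid resolution
#'
#' Rebuilds the grid over the default limits at several axis sizes,
#' solves each, and records the held-out RMSE per polynomial order —
#' the check that the default 68-per-axis resolution is fine enough for
#' the 0.5 ms selection threshold. Sizes from 6x6 (36 points) up to
#' 202x202 (40,804 points) are meaningful; the solved fraction is
#' roughly constant across sizes because the feasible region is a fixed
#' geometric fraction of the square.
#'
#' @param axis_sizes integer vector of per-axis point counts (>= 2).
#' @param orders polynomial orders to fit at each size.
#' @param start,stop grid limits (s), defaults as in [grid_spec()].
#' @param train_fraction,seed split settings.
#' @return Data frame with columns `n_axis`, `n_total`, `n_solved`,
#'   `order`, `rmse`, `r_squared`.
#' @export
grid_sensitivity <- function(axis_sizes, orders = 1:8, start = 0.0025,
                             stop = 0.505, train_fraction = 0.85,
                             seed = 42L) {
  stopifnot(all(axis_sizes >= 2))
  do.call(rbind, lapply(axis_sizes, function(m) {
    spec <- grid_spec(start, stop, (stop - start) / (m - 1))
    grid <- solve_grid(spec)
    do.call(rbind, lapply(orders, function(n) {
      fit <- fit_tg_surrogate(grid, order = n,
                              train_fraction = train_fraction, seed = seed)
      data.frame(n_axis = m, n_total = grid$n_total,
                 n_solved = grid$n_solved, order = as.integer(n),
                 rmse = fit$rmse, r_squared = fit$r_squared)
    }))
  }))
}
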