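#' Extract the empirical feasibility boundary from a solved grid
#'
#' For every `tce` axis value with at least one solvable point, returns
#' the smallest `tfe` that admitted a solution. On the default grid this
#' yields 68 pairs tracing the feasibility boundary of the sine-wave
#' model. Each extracted `tfe` lies at or above the analytic line
#' `boundary_ratio_analytic() * tce`, overshooting it by less than one
#' grid spacing (discretisation).
#'
#' @param grid a `tg_grid` from [solve_grid()].
#' @return Data frame with columns `tce`, `tfe` (s), one row per axis
#'   value that has any solution.
#' @export
extract_boundary_points <- function(grid) {
  stopifnot(inherits(grid, "tg_grid"))
  pts <- grid$points[!is.na(grid$points$tg), ]
  if (nrow(pts) == 0) {
    stop("grid contains no solved points; cannot extract a boundary",
         call. = FALSE)
  }
  min_tfe <- tapply(pts$tfe, factor(pts$tce, levels = grid$axis), min)
  keep <- !is.na(min_tfe)
  data.frame(tce = grid$axis[keep], tfe = as.numeric(min_tfe[keep]),
             row.names = NULL)
}

#' Fit the through-origin boundary line
#'
#' Ordinary least squares fit of `tfe = slope * tce` (intercept pinned
#' to zero: a null `tce` forces a null `tfe`) on a random 85% training
#' subset of the boundary points; the coefficient of determination and
#' RMSE are computed on the held-out 15%. On the default grid the slope
#' is about 0.795, above the analytic ratio 0.7836 because the discrete
#' boundary points overshoot the true line by up to one grid spacing.
#'
#' For the no-intercept model, R^2 is computed against the zero
#' baseline (`1 - sum(res^2) / sum(tfe^2)`), the convention consistent
#' with a fit constrained through the origin.
#'
#' @param points data frame with columns `tce`, `tfe` (s), typically
#'   from [extract_boundary_points()].
#' @param train_fraction fraction of points used for training;
#'   training-set size is `round(train_fraction * n)`.
#' @param seed integer seed for the random split (simple random
#'   sampling without replacement); recorded in the result.
#' @return An object of class `boundary_fit`: `slope`, `r_squared`,
#'   `rmse` (s, held-out), `train_idx`, `test_idx`, `seed`, `n`.
#' @export
fit_boundary <- function(points, train_fraction = 0.85, seed = 42L) {
  stopifnot(is.data.frame(points), all(c("tce", "tfe") %in% names(points)))
  n <- nrow(points)
  if (n < 2) {
    stop("need at least 2 boundary points to fit", call. = FALSE)
  }
  n_train <- max(1L, min(n - 1L, round(train_fraction * n)))
  train_idx <- sort(with_seed(seed, sample.int(n, n_train)))
  test_idx <- setdiff(seq_len(n), train_idx)
  tr <- points[train_idx, ]
  te <- points[test_idx, ]
  slope <- sum(tr$tce * tr$tfe) / sum(tr$tce^2)
  res <- te$tfe - slope * te$tce
  structure(list(slope = slope,
                 r_squared = 1 - sum(res^2) / sum(te$tfe^2),
                 rmse = sqrt(mean(res^2)),
                 train_idx = train_idx, test_idx = test_idx,
                 seed = seed, n = n),
            class = "boundary_fit")
}

#' @export
print.boundary_fit <- function(x, ...) {
  cat("Through-origin boundary fit: tfe = slope * tce\n")
  cat(sprintf("  slope      %.4f  (analytic ratio %.4f)\n",
              x$slope, boundary_ratio_analytic()))
  cat(sprintf("  held-out   RMSE %.2f ms,  R^2 %.1f%%  (n = %d, %d held out)\n",
              x$rmse * 1000, x$r_squared * 100, x$n, length(x$test_idx)))
  invisible(x)
}

#' @export
coef.boundary_fit <- function(object, ...) c(slope = object$slope)

#' Predict the boundary tfe for given tce values
#'
#' @param object a `boundary_fit`.
#' @param newdata numeric vector of `tce` values (s), or a data frame
#'   with a `tce` column.
#' @param ... unused.
#' @return Predicted minimal feasible `tfe` (s).
#' @export
predict.boundary_fit <- function(object, newdata, ...) {
  tce <- if (is.data.frame(newdata)) newdata$tce else newdata
  object$slope * tce
}

#' Serialise a boundary fit to JSON
#'
#' @param fit a `boundary_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_boundary <- function(fit, path) {
  stopifnot(inherits(fit, "boundary_fit"))
  jsonlite::write_json(
    list(schema = 1L, type = "boundary_fit",
         slope = fit$slope, r_squared = fit$r_squared,
         rmse_ms = fit$rmse * 1000, n = fit$n, seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
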