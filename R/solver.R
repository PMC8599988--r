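#' Grid specification for the effective-timing plane
#'
#' Defines a square grid of `(tce, tfe)` values. The default covers
#' 2.5 ms to 505 ms with 7.5 ms spacing: 68 values per axis, 4,624
#' points, wide enough for contact times of 100-400 ms and flight times
#' of 0-250 ms including atypical runners.
#'
#' Axis values are generated as `start + i * spacing` for integer `i`,
#' so the point count is immune to floating-point drift.
#'
#' @param start smallest axis value (s), strictly positive.
#' @param stop largest axis value (s).
#' @param spacing grid spacing (s), strictly positive.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(start = 0.0025, stop = 0.505, spacing = 0.0075) {
  stopifnot(start > 0, spacing > 0, stop >= start)
  structure(list(start = start, stop = stop, spacing = spacing),
            class = "grid_spec")
}

#' Axis values of a grid specification
#'
#' @param spec a [grid_spec()].
#' @return Numeric vector of axis values (s);
#'   `floor((stop - start) / spacing) + 1` of them.
#' @export
grid_axis <- function(spec) {
  n <- floor((spec$stop - spec$start) / spec$spacing + 1e-9) + 1
  spec$start + (seq_len(n) - 1) * spec$spacing
}

#' @export
print.grid_spec <- function(x, ...) {
  ax <- grid_axis(x)
  cat(sprintf("Grid: %.1f to %.1f ms, spacing %.2f ms (%d x %d = %d points)\n",
              x$start * 1000, x$stop * 1000, x$spacing * 1000,
              length(ax), length(ax), length(ax)^2))
  invisible(x)
}

#' Solve the crossing equation for tg at one effective-timing pair
#'
#' Finds the body-weight crossing time `tg` as the root of
#' [eq1_residual()] on the physical interval `(0, tfe / 2]` (the upper
#' cap enforces non-negative flight time). The residual falls from
#' `+Inf` at `tg -> 0+`; the root is bracketed between 0 and the
#' residual's minimiser over the interval ([stats::optimize()]), then
#' located with Brent's method ([stats::uniroot()]). If the residual
#' minimum over the interval stays positive, no physical solution
#' exists — this happens exactly when `tfe` falls below about
#' `0.7836 * tce` (see [boundary_ratio_analytic()]).
#'
#' @param tce,tfe effective contact and flight times (s); vectorised,
#'   recycled to common length.
#' @param tol convergence tolerance on `tg` (s).
#' @param eps lower bracket end (s); guards the singularity at 0.
#' @param max_iter iteration cap for the root search.
#' @return Numeric vector of `tg` values (s); `NA` marks pairs with no
#'   solution (a legitimate outcome, not an error). Solved values
#'   satisfy `0 < tg <= tfe / 2`.
#' @examples
#' solve_tg(0.2, 0.2) * 1000  # about 43.1 ms
#' solve_tg(0.2, 0.1)         # infeasible: NA
#' @export
solve_tg <- function(tce, tfe, tol = 1e-12, eps = 1e-9, max_iter = 200L) {
  stopifnot(tce > 0, tfe > 0)
  n <- max(length(tce), length(tfe))
  tce <- rep_len(tce, n)
  tfe <- rep_len(tfe, n)
  vapply(seq_len(n), function(k) {
    .solve_tg_one(tce[k], tfe[k], tol = tol, eps = eps, max_iter = max_iter)
  }, numeric(1))
}

.solve_tg_one <- function(tce, tfe, tol, eps, max_iter) {
  hi <- tfe / 2
  if (hi <= eps) return(NA_real_)
  f <- function(tg) eq1_residual(tg, tce, tfe)
  opt <- stats::optimize(f, c(eps, hi), tol = tol)
  f_min <- opt$objective
  x_min <- opt$minimum
  # optimize never lands exactly on an endpoint; the minimum can sit there
  f_hi <- f(hi)
  if (f_hi < f_min) {
    f_min <- f_hi
    x_min <- hi
  }
  if (f_min > 0) return(NA_real_)
  if (f_min == 0) return(x_min)
  root <- stats::uniroot(f, c(eps, x_min), tol = tol, maxiter = max_iter)
  if (root$iter >= max_iter && abs(root$f.root) > 1e-6) {
    stop(sprintf("root search failed to converge at tce = %g, tfe = %g",
                 tce, tfe), call. = FALSE)
  }
  root$root
}

#' Solve the crossing equation over a full grid
#'
#' Runs [solve_tg()] at every point of the `tce x tfe` grid. With the
#' default grid, 4,624 points are attempted and 1,814 of them have no
#' solution with non-negative flight time (they lie below the
#' feasibility boundary); the remaining 2,810 carry the `tg` surface
#' used to train the polynomial surrogate.
#'
#' @param spec a [grid_spec()].
#' @param tol,eps,max_iter passed to [solve_tg()].
#' @return An object of class `tg_grid`: list with `points` (data frame
#'   `tce`, `tfe`, `tg`, `tg` `NA` where unsolved), `axis`, `spec`,
#'   `n_total`, `n_solved`, `n_unsolved`, `tol`.
#' @export
solve_grid <- function(spec = grid_spec(), tol = 1e-12, eps = 1e-9,
                       max_iter = 200L) {
  stopifnot(inherits(spec, "grid_spec"))
  ax <- grid_axis(spec)
  pts <- expand.grid(tce = ax, tfe = ax, KEEP.OUT.ATTRS = FALSE)
  pts$tg <- solve_tg(pts$tce, pts$tfe, tol = tol, eps = eps,
                     max_iter = max_iter)
  structure(list(points = pts, axis = ax, spec = spec,
                 n_total = nrow(pts),
                 n_solved = sum(!is.na(pts$tg)),
                 n_unsolved = sum(is.na(pts$tg)),
                 tol = tol),
            class = "tg_grid")
}

#' @export
print.tg_grid <- function(x, ...) {
  print(x$spec)
  cat(sprintf("Solved: %d of %d points (%d infeasible, below tfe = %.4f tce)\n",
              x$n_solved, x$n_total, x$n_unsolved, boundary_ratio_analytic()))
  invisible(x)
}

#' @export
as.data.frame.tg_grid <- function(x, ...) x$points

#' Write / read a solved grid as CSV
#'
#' Columns `tce_ms`, `tfe_ms`, `tg_ms`, one row per grid point, `tg_ms`
#' empty for infeasible points. Acts as a cache for the downstream
#' boundary and surrogate fits.
#'
#' @param grid a `tg_grid` from [solve_grid()].
#' @param path file path.
#' @return `write_grid` returns `path` invisibly; `read_grid` returns a
#'   `tg_grid`.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "tg_grid"))
  out <- data.frame(tce_ms = grid$points$tce * 1000,
                    tfe_ms = grid$points$tfe * 1000,
                    tg_ms = grid$points$tg * 1000)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tce_ms", "tfe_ms", "tg_ms")
  if (!all(need %in% names(df))) {
    stop("grid CSV must have columns tce_ms, tfe_ms, tg_ms", call. = FALSE)
  }
  pts <- data.frame(tce = df$tce_ms / 1000, tfe = df$tfe_ms / 1000,
                    tg = df$tg_ms / 1000)
  ax <- sort(unique(pts$tce))
  spacing <- if (length(ax) > 1) stats::median(diff(ax)) else 1e-3
  structure(list(points = pts, axis = ax,
                 spec = grid_spec(min(ax), max(ax), spacing),
                 n_total = nrow(pts),
                 n_solved = sum(!is.na(pts$tg)),
                 n_unsolved = sum(is.na(pts$tg)),
                 tol = NA_real_),
            class = "tg_grid")
}
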