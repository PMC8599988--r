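# Independent oracles, deliberately written without calling the package's
# own residual/solver code paths.

# Residual of the body-weight crossing equation, written from scratch.
oracle_residual <- function(tg, tce, tfe) {
  1 / sin(pi * tg / (tce + 2 * tg)) -
    (pi / 2) * ((tfe - 2 * tg) / (tce + 2 * tg) + 1)
}

# Naive bisection solver: scan (eps, tfe/2] for a sign change, then bisect.
oracle_bisect_tg <- function(tce, tfe, iters = 100) {
  lo <- 1e-9
  hi <- tfe / 2
  xs <- seq(lo, hi, length.out = 400)
  fx <- vapply(xs, oracle_residual, numeric(1), tce = tce, tfe = tfe)
  first_neg <- which(fx <= 0)[1]
  if (is.na(first_neg)) return(NA_real_)
  hi <- xs[first_neg]
  if (first_neg > 1) lo <- xs[first_neg - 1]
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (oracle_residual(mid, tce, tfe) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Feasibility ratio by bisection on sin(pi * r / (2 * (1 + r))) = 2 / pi.
oracle_boundary_ratio <- function(iters = 200) {
  g <- function(r) sin(pi * r / (2 * (1 + r))) - 2 / pi
  lo <- 0.5; hi <- 1.5
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random feasible effective-timing pairs (above the feasibility line).
random_feasible_pairs <- function(n, seed = 7) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    tce <- runif(n, 0.05, 0.5)
    tfe <- tce * runif(n, 0.80, 2.0)
    data.frame(tce = tce, tfe = tfe)
  })
}
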