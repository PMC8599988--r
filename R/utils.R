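# Run code with a local RNG seed, restoring global RNG state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Least squares via SVD with per-column equilibration: each column is
# scaled to unit Euclidean norm before the decomposition, which makes
# the solve invariant to the wildly different magnitudes of high-order
# monomial columns. Singular values below the usual machine-precision
# cutoff are truncated (pseudo-inverse); structural deficiency (fewer
# rows than columns) is an error.
lstsq <- function(X, y, context = "least-squares problem") {
  if (nrow(X) < ncol(X)) {
    stop(sprintf("rank-deficient %s (%d columns, only %d rows)",
                 context, ncol(X), nrow(X)), call. = FALSE)
  }
  norms <- sqrt(colSums(X^2))
  norms[norms == 0] <- 1
  Xs <- sweep(X, 2, norms, "/")
  dec <- svd(Xs)
  tol <- max(dim(X)) * max(dec$d) * .Machine$double.eps
  d_inv <- ifelse(dec$d > tol, 1 / dec$d, 0)
  drop(dec$v %*% (d_inv * (t(dec$u) %*% y))) / norms
}
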