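#' Reconstruct stride timings for a dataset of effective-timing pairs
#'
#' Runs each `(tce, tfe)` pair through the surrogate to get `tg`, then
#' through [reconstruct_from_tg()] to recover `tc` and `tf`. Rows that
#' cannot be reconstructed — infeasible pairs, or predicted `tg`
#' implying negative flight time — are skipped and collected in the
#' `skipped` attribute rather than failing the whole dataset.
#'
#' @param model a `tg_surrogate`.
#' @param pairs data frame with columns `tce`, `tfe` (s).
#' @return Data frame of stride timings (`tc`, `tf`, `tce`, `tfe`,
#'   `tg`, all s), one row per reconstructable input row; attribute
#'   `skipped` is a data frame of row numbers and reasons.
#' @export
reconstruct_dataset <- function(model, pairs) {
  stopifnot(inherits(model, "tg_surrogate"), is.data.frame(pairs),
            all(c("tce", "tfe") %in% names(pairs)))
  rows <- vector("list", nrow(pairs))
  skipped <- list()
  for (k in seq_len(nrow(pairs))) {
    row <- tryCatch({
      tg <- suppressWarnings(predict(model, pairs[k, c("tce", "tfe")]))
      tg <- max(tg, 0)  # surrogate can undershoot 0 by its own RMSE
      reconstruct_from_tg(pairs$tce[k], pairs$tfe[k], tg)
    }, error = function(e) e)
    if (inherits(row, "error")) {
      skipped[[length(skipped) + 1]] <-
        data.frame(row = k, reason = conditionMessage(row))
    } else {
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(tc = numeric(0), tf = numeric(0), tce = numeric(0),
                      tfe = numeric(0), tg = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(row = integer(0), reason = character(0))
  out
}

#' Bland-Altman agreement between measured and reconstructed timings
#'
#' Standard Bland-Altman analysis of `measured - reconstructed`
#' differences: systematic bias (mean difference), 95% limits of
#' agreement `bias +/- 1.96 * sd`, and confidence intervals using the t
#' quantile — `bias +/- t(.975, n-1) * sd / sqrt(n)` for the bias and
#' `loa +/- t(.975, n-1) * sd * sqrt(3 / n)` for each limit. RMSE of
#' the differences and Cohen's d between the two series (pooled-SD
#' denominator, see [cohens_d()]) are reported alongside. The relative
#' RMSE uses the mean of the measured series as denominator and is
#' informational.
#'
#' @param measured,reconstructed equal-length numeric vectors (s),
#'   `n >= 2`.
#' @return An object of class `agreement_report` with fields `n`,
#'   `bias`, `sd_diff`, `loa_lower`, `loa_upper`, `ci_bias`,
#'   `ci_loa_lower`, `ci_loa_upper`, `rmse`, `rmse_pct`, `cohens_d`,
#'   plus the input series for plotting. Durations in seconds.
#' @export
bland_altman <- function(measured, reconstructed) {
  if (length(measured) != length(reconstructed)) {
    stop("`measured` and `reconstructed` must have equal length",
         call. = FALSE)
  }
  n <- length(measured)
  if (n < 2) stop("need at least 2 paired observations", call. = FALSE)
  d <- measured - reconstructed
  bias <- mean(d)
  sd_d <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  se_bias <- sd_d / sqrt(n)
  se_loa <- sd_d * sqrt(3 / n)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  structure(list(n = n, bias = bias, sd_diff = sd_d,
                 loa_lower = loa[1], loa_upper = loa[2],
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
                 ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa,
                 rmse = sqrt(mean(d^2)),
                 rmse_pct = 100 * sqrt(mean(d^2)) / mean(measured),
                 cohens_d = if (stats::sd(measured) + stats::sd(reconstructed) > 0)
                   cohens_d(measured, reconstructed) else 0,
                 measured = measured, reconstructed = reconstructed),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  ms <- function(v) v * 1000
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias        %6.1f ms  [%.1f, %.1f]\n",
              ms(x$bias), ms(x$ci_bias[1]), ms(x$ci_bias[2])))
  cat(sprintf("  LoA lower   %6.1f ms  [%.1f, %.1f]\n",
              ms(x$loa_lower), ms(x$ci_loa_lower[1]), ms(x$ci_loa_lower[2])))
  cat(sprintf("  LoA upper   %6.1f ms  [%.1f, %.1f]\n",
              ms(x$loa_upper), ms(x$ci_loa_upper[1]), ms(x$ci_loa_upper[2])))
  cat(sprintf("  RMSE        %6.1f ms (%.1f%%)\n", ms(x$rmse), x$rmse_pct))
  cat(sprintf("  Cohen's d   %6.2f\n", x$cohens_d))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Scatter of pairwise means against differences with bias and limits
#' of agreement as horizontal lines, in milliseconds.
#'
#' @param x an `agreement_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.agreement_report <- function(x, ...) {
  avg <- (x$measured + x$reconstructed) / 2 * 1000
  d <- (x$measured - x$reconstructed) * 1000
  graphics::plot(avg, d, xlab = "mean of methods (ms)",
                 ylab = "measured - reconstructed (ms)", ...)
  graphics::abline(h = x$bias * 1000, lty = 1)
  graphics::abline(h = c(x$loa_lower, x$loa_upper) * 1000, lty = 2)
  invisible(x)
}

#' Cohen's d standardised mean difference
#'
#' `(mean(a) - mean(b))` divided by the pooled standard deviation of
#' the two series. Note the denominator is the pooled SD of the
#' measurements, not the SD of paired differences; with typical
#' contact-time data the two conventions differ widely.
#'
#' @param a,b numeric vectors, each of length `>= 2`.
#' @return Dimensionless effect size; antisymmetric in its arguments.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2, nb >= 2)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) {
    stop("pooled standard deviation is zero; effect size undefined",
         call. = FALSE)
  }
  (mean(a) - mean(b)) / sp
}
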