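#' Load effective timings from CSV
#'
#' Reads a CSV with one step per row, columns `tce_ms`, `tfe_ms`
#' (milliseconds). Any further `*_ms` columns (for example ground-truth
#' `tc_ms`, `tf_ms`) are carried along, converted to seconds with the
#' suffix dropped. Rows with missing, non-numeric, or non-positive
#' `tce_ms` / `tfe_ms` are rejected with their line numbers.
#'
#' @param path CSV file path (comma-separated, UTF-8, header required).
#' @return Data frame with columns `tce`, `tfe` (s) plus any converted
#'   extras.
#' @export
load_timings <- function(path) {
  df <- utils::read.csv(path)
  need <- c("tce_ms", "tfe_ms")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("missing required column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(data.frame(tce = numeric(0), tfe = numeric(0)))
  }
  bad <- !is.finite(df$tce_ms) | !is.finite(df$tfe_ms) |
    df$tce_ms <= 0 | df$tfe_ms <= 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    stop(sprintf("invalid timing row(s) at line(s) %s (need finite positive tce_ms, tfe_ms)",
                 paste(which(bad) + 1L, collapse = ", ")), call. = FALSE)
  }
  ms_cols <- grep("_ms$", names(df), value = TRUE)
  out <- as.data.frame(lapply(df[ms_cols], function(v) v / 1000))
  names(out) <- sub("_ms$", "", ms_cols)
  front <- c("tce", "tfe")
  out[, c(front, setdiff(names(out), front)), drop = FALSE]
}

#' Save / load a polynomial surrogate as JSON
#'
#' The model file is versioned JSON (`schema: 1`) holding the order,
#' the units convention (only `"s"` is accepted), the coefficients as
#' `(i, j, value)` triples in graded lexicographic order, and training
#' metadata (grid spec, seed, train fraction, held-out RMSE and R^2).
#' A round trip reproduces predictions bitwise.
#'
#' @param model a `tg_surrogate`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the `tg_surrogate`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tg_surrogate"))
  doc <- list(
    schema = 1L, type = "tg_surrogate", units = model$units,
    order = model$order,
    coefficients = data.frame(i = model$exponents$i, j = model$exponents$j,
                              value = unname(model$alpha)),
    training = list(grid_start = model$spec$start,
                    grid_stop = model$spec$stop,
                    grid_spacing = model$spec$spacing,
                    seed = model$seed,
                    train_fraction = model$train_fraction,
                    n_points = model$n_points, n_train = model$n_train,
                    rmse = model$rmse, r_squared = model$r_squared),
    envelope = model$envelope,
    package_version = as.character(utils::packageVersion("grftimes")))
  # 17 significant digits: lossless for doubles, so a round trip
  # reproduces predictions bitwise
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop(sprintf("not a valid model file: %s",
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (!identical(doc$type, "tg_surrogate") || is.null(doc$schema) ||
      doc$schema != 1) {
    stop("not a schema-1 tg_surrogate model file", call. = FALSE)
  }
  if (!identical(doc$units, "s")) {
    stop(sprintf("unsupported units '%s' (only 's' accepted)", doc$units),
         call. = FALSE)
  }
  co <- doc$coefficients
  want <- surrogate_exponents(doc$order)
  if (!identical(as.integer(co$i), as.integer(want$i)) ||
      !identical(as.integer(co$j), as.integer(want$j))) {
    stop("coefficient exponents do not match the declared order",
         call. = FALSE)
  }
  alpha <- co$value
  names(alpha) <- sprintf("tce^%d.tfe^%d", want$i, want$j)
  tr <- doc$training
  structure(list(alpha = alpha, exponents = want,
                 order = as.integer(doc$order), units = doc$units,
                 rmse = tr$rmse, r_squared = tr$r_squared,
                 n_points = tr$n_points, n_train = tr$n_train,
                 train_fraction = tr$train_fraction, seed = tr$seed,
                 spec = grid_spec(tr$grid_start, tr$grid_stop,
                                  tr$grid_spacing),
                 envelope = list(min = doc$envelope$min,
                                 max = doc$envelope$max)),
            class = "tg_surrogate")
}

#' The packaged default surrogate
#'
#' Loads the order-8 surrogate shipped with the package, refit by this
#' package's own pipeline on the default grid (split seed 42). The
#' coefficients are a refit, not a transcription: published coefficient
#' tables of this model are not machine-readable to full precision, so
#' shipping a refit keeps model file and code consistent.
#'
#' @return A `tg_surrogate` of order 8.
#' @export
default_surrogate <- function() {
  load_model(system.file("extdata", "tg_surrogate_order8.json",
                         package = "grftimes", mustWork = TRUE))
}
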