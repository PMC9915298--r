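#' Find stationary windows in a raw recording
#'
#' Scans the recording in non-overlapping windows and returns the mean
#' acceleration vector of every window in which all three axes have a
#' standard deviation below `sd_threshold_mg`. Windows containing clipped
#' samples (absolute value at or above `clip_range_g`) are discarded, since
#' sustained or abnormally high values cannot reflect a resting device.
#' These window means are the input points for [fit_calibration()].
#'
#' @param rec a [raw_recording()] (must be longer than one window).
#' @param window_s window length in seconds (default 10).
#' @param sd_threshold_mg per-axis stillness criterion in mg (default 13).
#' @param clip_range_g saturation limit in g used to reject clipped windows;
#'   `NULL` disables the check.
#' @return numeric matrix with columns `x`, `y`, `z`: one row per stationary
#'   window, in g. The attribute `n_windows` records how many windows were
#'   scanned.
#' @export
find_stationary_windows <- function(rec, window_s = 10, sd_threshold_mg = 13,
                                    clip_range_g = 4) {
  stopifnot(window_s > 0)
  n <- nrow(rec$data)
  if (n == 0L) stop("empty recording")
  spw <- as.integer(round(window_s * rec$sample_rate_hz))
  nw <- n %/% spw
  if (nw < 1L) stop("recording shorter than one window")
  thr <- sd_threshold_mg / 1000
  keep <- rep(TRUE, nw)
  means <- matrix(0, nw, 3L, dimnames = list(NULL, c("x", "y", "z")))
  used <- seq_len(nw * spw)
  for (j in 1:3) {
    m <- matrix(rec$data[used, j], nrow = spw)
    mu <- .colMeans(m, spw, nw)
    v <- .colMeans(m * m, spw, nw) - mu^2
    sdj <- sqrt(pmax(v, 0) * spw / (spw - 1))
    means[, j] <- mu
    keep <- keep & (sdj < thr)
    if (!is.null(clip_range_g)) {
      mx <- apply(abs(m), 2L, max)
      keep <- keep & (mx < clip_range_g)
    }
  }
  out <- means[keep, , drop = FALSE]
  attr(out, "n_windows") <- nw
  out
}

.identity_model <- function(points = NULL) {
  pe <- if (!is.null(points) && nrow(points) > 0) {
    mean(abs(sqrt(rowSums(points^2)) - 1))
  } else NA_real_
  structure(list(offset_g = c(0, 0, 0), gain = c(1, 1, 1),
                 post_error_g = pe,
                 n_stationary_windows = if (is.null(points)) 0L else nrow(points),
                 sphere_coverage_ok = FALSE, converged = FALSE,
                 iterations = 0L),
            class = "calibration_model")
}

#' Fit an auto-calibration model to stationary points
#'
#' Estimates a per-axis linear correction (`gain * value + offset`) that
#' moves the stationary-window mean vectors onto the unit (1 g) sphere,
#' using local gravity as the reference: each iteration projects the current
#' calibrated points onto the sphere and re-fits each axis by least squares
#' against its projection, until the change in residual falls below `tol`.
#' The fit is attempted only when enough points are available and they cover
#' the sphere (both signs beyond `coverage_mg` on every axis); otherwise an
#' identity model flagged `converged = FALSE` is returned, and the caller
#' may substitute back-up coefficients from another wear of the same device.
#'
#' @param points matrix of stationary 3-vectors in g, as returned by
#'   [find_stationary_windows()].
#' @param min_points minimum number of stationary points required.
#' @param coverage_mg sphere-coverage requirement per axis, mg.
#' @param max_iter,tol iteration controls.
#' @return object of class `calibration_model`: offsets (g), gains,
#'   `post_error_g` (mean absolute deviation of calibrated point magnitudes
#'   from 1 g), `n_stationary_windows`, `sphere_coverage_ok`, `converged`.
#' @export
fit_calibration <- function(points, min_points = 10, coverage_mg = 300,
                            max_iter = 100, tol = 1e-9) {
  points <- as.matrix(points)
  if (is.null(points) || nrow(points) < min_points) {
    return(.identity_model(points))
  }
  cov_g <- coverage_mg / 1000
  coverage <- all(apply(points, 2L, min) < -cov_g) &&
    all(apply(points, 2L, max) > cov_g)
  if (!coverage) return(.identity_model(points))

  gain <- c(1, 1, 1); offset <- c(0, 0, 0)
  err_prev <- Inf; it <- 0L
  for (it in seq_len(max_iter)) {
    cal <- sweep(sweep(points, 2L, gain, `*`), 2L, offset, `+`)
    nrm <- sqrt(rowSums(cal^2))
    target <- cal / nrm
    for (j in 1:3) {
      fit <- stats::lm.fit(cbind(1, cal[, j]), target[, j])
      offset[j] <- offset[j] * fit$coefficients[2L] + fit$coefficients[1L]
      gain[j] <- gain[j] * fit$coefficients[2L]
    }
    err <- mean(abs(nrm - 1))
    if (abs(err_prev - err) < tol) break
    err_prev <- err
  }
  cal <- sweep(sweep(points, 2L, gain, `*`), 2L, offset, `+`)
  structure(list(offset_g = unname(offset), gain = unname(gain),
                 post_error_g = mean(abs(sqrt(rowSums(cal^2)) - 1)),
                 n_stationary_windows = nrow(points),
                 sphere_coverage_ok = TRUE, converged = TRUE,
                 iterations = it),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(paste0("<calibration_model> converged=%s coverage=%s ",
                     "windows=%d\n  gain  = (%.5f, %.5f, %.5f)\n",
                     "  offset= (%.2f, %.2f, %.2f) mg\n",
                     "  post-calibration error = %.3f mg\n"),
              x$converged, x$sphere_coverage_ok, x$n_stationary_windows,
              x$gain[1], x$gain[2], x$gain[3],
              1000 * x$offset_g[1], 1000 * x$offset_g[2],
              1000 * x$offset_g[3], 1000 * x$post_error_g))
  invisible(x)
}

#' Apply a calibration model to a recording
#'
#' Maps every sample per axis as `gain * value + offset`. By default the
#' model must have converged; set `force = TRUE` to apply an identity or
#' externally supplied (back-up) model regardless.
#'
#' @param rec a [raw_recording()].
#' @param model a `calibration_model` (from [fit_calibration()]) or any list
#'   with finite `gain` and `offset_g`.
#' @param force apply even if `model$converged` is `FALSE`.
#' @return the calibrated [raw_recording()]; the model used is attached as
#'   attribute `calibration`.
#' @export
apply_calibration <- function(rec, model, force = FALSE) {
  if (!all(is.finite(model$gain)) || !all(is.finite(model$offset_g))) {
    stop("non-finite calibration model")
  }
  if (!isTRUE(model$converged) && !force) {
    stop("model did not converge; pass force = TRUE to apply anyway")
  }
  data <- sweep(sweep(rec$data, 2L, model$gain, `*`), 2L,
                model$offset_g, `+`)
  out <- raw_recording(rec$start_time, rec$sample_rate_hz, data)
  attr(out, "calibration") <- model
  out
}

#' Post-calibration error of a point set under a model
#'
#' Mean absolute deviation of calibrated stationary-point magnitudes from
#' 1 g — the quantity used as the file-inclusion criterion (< 0.02 g).
#'
#' @param points stationary-window means, in g.
#' @param model a `calibration_model`; defaults to the identity.
#' @return numeric scalar, in g.
#' @export
calibration_error <- function(points, model = .identity_model()) {
  cal <- sweep(sweep(as.matrix(points), 2L, model$gain, `*`), 2L,
               model$offset_g, `+`)
  mean(abs(sqrt(rowSums(cal^2)) - 1))
}
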