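#' Sensor specification
#'
#' Describes the simulated device: sampling rate, dynamic range, white-noise
#' level and a per-axis linear distortion. The distortion maps the true
#' acceleration `a` to the measured value `gain * a + offset` (per axis),
#' which is what auto-calibration later has to undo. Defaults reflect a
#' thigh-worn activPAL-class logger: 20 Hz, +/-4 g.
#'
#' @param sample_rate_hz sampling frequency, Hz.
#' @param dynamic_range_g measurement range; samples are clipped to
#'   `+/- dynamic_range_g`.
#' @param noise_sd_mg standard deviation of additive white sensor noise, mg.
#' @param offset_g per-axis additive offset of the distortion, g
#'   (components must be below 0.25 g in magnitude).
#' @param gain per-axis multiplicative gain of the distortion
#'   (components in (0.8, 1.2)).
#' @return object of class `sensor_spec`.
#' @export
sensor_spec <- function(sample_rate_hz = 20, dynamic_range_g = 4,
                        noise_sd_mg = 3, offset_g = c(0, 0, 0),
                        gain = c(1, 1, 1)) {
  stopifnot(sample_rate_hz > 0, dynamic_range_g > 0, noise_sd_mg >= 0,
            length(offset_g) == 3L, length(gain) == 3L)
  if (any(abs(offset_g) >= 0.25)) stop("offset components must be < 0.25 g")
  if (any(gain <= 0.8 | gain >= 1.2)) stop("gain components must be in (0.8, 1.2)")
  structure(list(sample_rate_hz = sample_rate_hz,
                 dynamic_range_g = dynamic_range_g,
                 noise_sd_mg = noise_sd_mg,
                 offset_g = as.numeric(offset_g),
                 gain = as.numeric(gain)),
            class = "sensor_spec")
}

# --- orientation helpers -----------------------------------------------------
# The device sits on the anterior thigh; its longitudinal axis is mapped to z.
# Upright postures put gravity close to +z; seated/lying postures put it close
# to the x-y plane, with a free azimuth and a modest tilt.

.orient_upright <- function(max_tilt_deg = 15) {
  th <- runif(1, 0, max_tilt_deg) * pi / 180
  ph <- runif(1, 0, 2 * pi)
  c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
}

.orient_reclined <- function(azimuth, max_tilt_deg = 20) {
  tl <- runif(1, -max_tilt_deg, max_tilt_deg) * pi / 180
  c(cos(tl) * cos(azimuth), cos(tl) * sin(azimuth), sin(tl))
}

# next azimuth at least 30 degrees away from the previous one, so that
# consecutive still postures are geometrically distinct
.next_azimuth <- function(prev) {
  (prev + runif(1, pi / 6, 2 * pi - pi / 6)) %% (2 * pi)
}

.perp_unit <- function(u) {
  r <- c(u[2], -u[1], 0)
  if (sum(r^2) < 1e-12) r <- c(1, 0, 0)
  r / sqrt(sum(r^2))
}

# --- signal synthesis --------------------------------------------------------
# `segments` is a data.frame with one row per constant-orientation segment:
#   dur_s   : duration, a multiple of epoch_s except possibly the last row
#   ux,uy,uz: unit gravity direction in the sensor frame
#   mad_med, enmo_med : segment-type median epoch targets, mg
#   gamma   : ENMO log-spread / MAD log-spread coupling exponent
#   s_epoch : epoch-level lognormal sd of the target multiplier
#   lm_bout : segment-level log multiplier (drawn by the caller)
#   type    : key used to cache the (A, b) solver per target family
# Movement is a single band-limited (0.5-3 Hz) magnitude oscillation along
# gravity with a per-epoch amplitude solved from the target metric values,
# plus a weaker transverse oscillation that perturbs individual axes without
# materially changing the vector magnitude.
.synth_recording <- function(segments, start_time, sensor,
                             epoch_s = 5, transverse = 0.3) {
  rate <- sensor$sample_rate_hz
  sigma <- sensor$noise_sd_mg
  spe <- as.integer(round(epoch_s * rate))
  n_seg <- as.integer(round(segments$dur_s * rate))
  n <- sum(n_seg)
  if (n < 1L) stop("empty segment table")
  inv <- .mad_inverter(sigma)
  solvers <- new.env(parent = emptyenv())
  out <- matrix(0, nrow = n, ncol = 3L)
  pos <- 0L
  for (i in seq_len(nrow(segments))) {
    ni <- n_seg[i]
    if (ni < 1L) next
    key <- segments$type[i]
    if (is.null(solvers[[key]])) {
      solvers[[key]] <- .type_solver(segments$mad_med[i],
                                     segments$enmo_med[i],
                                     segments$gamma[i], sigma, inv)
    }
    ne <- as.integer(ceiling(ni / spe))
    lm <- segments$lm_bout[i] + rnorm(ne, 0, segments$s_epoch[i])
    ab <- solvers[[key]](lm)
    A <- rep(ab$A, each = spe)[seq_len(ni)] / 1000
    b <- rep(ab$b, each = spe)[seq_len(ni)] / 1000
    f1 <- runif(1, 0.5, 3); p1 <- runif(1, 0, 2 * pi)
    f2 <- runif(1, 0.5, 3); p2 <- runif(1, 0, 2 * pi)
    tt <- (seq_len(ni) - 1L) / rate
    dev <- b + A * sin(2 * pi * f1 * tt + p1)
    trn <- transverse * A * sin(2 * pi * f2 * tt + p2)
    u <- c(segments$ux[i], segments$uy[i], segments$uz[i])
    p <- .perp_unit(u)
    idx <- pos + seq_len(ni)
    s <- 1 + dev
    out[idx, 1L] <- u[1] * s + p[1] * trn
    out[idx, 2L] <- u[2] * s + p[2] * trn
    out[idx, 3L] <- u[3] * s + p[3] * trn
    pos <- pos + ni
  }
  sd_g <- sigma / 1000
  rng <- sensor$dynamic_range_g
  for (j in 1:3) {
    v <- sensor$gain[j] * out[, j] + sensor$offset_g[j]
    if (sd_g > 0) v <- v + rnorm(n, 0, sd_g)
    if (max(abs(range(v))) > rng) v <- pmin(pmax(v, -rng), rng)
    out[, j] <- v
  }
  raw_recording(start_time, rate, out)
}

# truncated standard normal draw (heavy-tail guard for between-participant
# amplitude multipliers)
.rnorm_trunc <- function(n, sd = 1, z_max = 2.5) {
  z <- rnorm(n)
  while (any(bad <- abs(z) > z_max)) z[bad] <- rnorm(sum(bad))
  z * sd
}

# mean of a lognormal(meanlog, sdlog) clamped to [lo, hi] (exact)
.capped_ln_mean <- function(meanlog, sdlog, lo, hi) {
  m <- exp(meanlog + sdlog^2 / 2)
  zlo <- (log(lo) - meanlog) / sdlog
  zhi <- (log(hi) - meanlog) / sdlog
  lo * pnorm(zlo) +
    m * (pnorm(zhi - sdlog) - pnorm(zlo - sdlog)) +
    hi * (1 - pnorm(zhi))
}

.rln_capped <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(exp(rnorm(n, meanlog, sdlog)), lo), hi)
}
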