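# Shared fixtures, built in code. The free-living evaluation cohort is
# expensive, so it is built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

t_origin <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")

# recording with prescribed magnitude trace along a fixed direction
mag_recording <- function(mag, rate = 20, dir = c(0, 0, 1),
                          start = t_origin) {
  raw_recording(start, rate, cbind(dir[1] * mag, dir[2] * mag, dir[3] * mag))
}

# epoch series built directly from values (5-s grid)
make_epoch_series <- function(enmo, mad = enmo, wear = "worn",
                              start = t_origin, epoch_s = 5) {
  n <- length(enmo)
  out <- data.frame(time = start + (seq_len(n) - 1L) * epoch_s,
                    enmo_mg = enmo, mad_mg = mad,
                    wear = rep(wear, length.out = n))
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("epoch_series", "data.frame")
  out
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# random unit vectors covering the sphere, for calibration point clouds
sphere_points <- function(n, noise_mg = 0) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  if (noise_mg > 0) v <- v + matrix(rnorm(3 * n, 0, noise_mg / 1000), ncol = 3)
  colnames(v) <- c("x", "y", "z")
  v
}

# the evaluation cohort: 38 participants, 36 with six full calendar days of
# continuous wear and miscalibrated sensors, 2 with recordings spanning no
# complete midnight-to-midnight day
the_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_freeliving_cohort(n = 38, days = 6,
                                                   n_invalid = 2, seed = 49L)
  }
  .fixtures$cohort
}

# one small free-living simulation reused by calibration / metrics tests
small_freeliving <- function() {
  if (is.null(.fixtures$small)) {
    .fixtures$small <- generate_freeliving_recording(
      1, sensor_spec(noise_sd_mg = 3), seed = 7L)
  }
  .fixtures$small
}
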