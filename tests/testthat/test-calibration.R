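test_that("stationary-window detection matches a brute-force rescan", {
  set.seed(1)
  # 2 min quiet (noise 3 mg), 2 min strong movement, 1 min quiet
  quiet1 <- matrix(rnorm(3 * 2400, 0, 0.003), ncol = 3)
  quiet1[, 3] <- quiet1[, 3] + 1
  move <- cbind(0.3 * sin(2 * pi * 2 * (1:2400) / 20), 0,
                1 + 0.2 * sin(2 * pi * 1.3 * (1:2400) / 20))
  quiet2 <- matrix(rnorm(3 * 1200, 0, 0.003), ncol = 3)
  quiet2[, 1] <- quiet2[, 1] + 1
  rec <- raw_recording(t_origin, 20, rbind(quiet1, move, quiet2))

  got <- find_stationary_windows(rec, window_s = 10, sd_threshold_mg = 13)
  # independent rescan with stats::sd over every 200-sample window
  spw <- 200L
  oracle <- NULL
  for (w in seq_len(nrow(rec$data) %/% spw)) {
    block <- rec$data[((w - 1) * spw + 1):(w * spw), ]
    if (all(apply(block, 2, sd) < 0.013)) {
      oracle <- rbind(oracle, colMeans(block))
    }
  }
  expect_equal(nrow(got), nrow(oracle))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12,
               ignore_attr = TRUE)
  # pure-noise stationary recording: every window returned
  all_q <- find_stationary_windows(
    raw_recording(t_origin, 20, quiet1), 10, 13)
  expect_equal(nrow(all_q), 12L)
  # continuous strong movement: none
  none <- find_stationary_windows(raw_recording(t_origin, 20, move), 10, 13)
  expect_equal(nrow(none), 0L)
  expect_error(find_stationary_windows(
    raw_recording(t_origin, 20, matrix(numeric(0), ncol = 3))), "empty")
})

test_that("perfect unit-sphere points fit to the identity", {
  set.seed(2)
  pts <- sphere_points(400)
  m <- fit_calibration(pts)
  expect_true(m$converged && m$sphere_coverage_ok)
  expect_equal(m$gain, c(1, 1, 1), tolerance = 1e-6)
  expect_equal(m$offset_g, c(0, 0, 0), tolerance = 1e-6)
  expect_lt(m$post_error_g, 1e-6)
})

test_that("injected offsets and gains are recovered on well-covered points", {
  set.seed(3)
  gain <- c(1.02, 0.98, 1.00); offset <- c(0.020, -0.030, 0.010)
  truth <- sphere_points(500, noise_mg = 2)
  measured <- sweep(sweep(truth, 2, gain, `*`), 2, offset, `+`)
  m <- fit_calibration(measured)
  expect_true(m$converged)
  # fitted model must invert the distortion
  expect_lt(max(abs(m$gain * gain - 1)), 0.005)
  expect_lt(max(abs(m$offset_g - (-offset / gain))), 0.002)
  expect_lt(m$post_error_g, 0.005)
})

test_that("degenerate point sets return a non-converged identity model", {
  few <- sphere_points(5)
  m1 <- fit_calibration(few)
  expect_false(m1$converged)
  expect_equal(m1$gain, c(1, 1, 1))
  # one hemisphere only: no sphere coverage
  set.seed(4)
  hemi <- sphere_points(300)
  hemi[, 3] <- abs(hemi[, 3])
  m2 <- fit_calibration(hemi)
  expect_false(m2$converged)
  expect_false(m2$sphere_coverage_ok)
})

test_that("apply_calibration maps axes linearly and is invertible", {
  sim <- small_freeliving()
  rec <- sim$recording
  ident <- list(gain = c(1, 1, 1), offset_g = c(0, 0, 0), converged = TRUE)
  expect_equal(apply_calibration(rec, ident)$data, rec$data)
  model <- list(gain = c(1.01, 0.99, 1.02), offset_g = c(0.01, -0.02, 0.005),
                converged = TRUE)
  inv <- list(gain = 1 / model$gain, offset_g = -model$offset_g / model$gain,
              converged = TRUE)
  back <- apply_calibration(apply_calibration(rec, model), inv)
  expect_lt(max(abs(back$data - rec$data)), 1e-12)
  expect_error(apply_calibration(rec, list(gain = c(NA, 1, 1),
                                           offset_g = c(0, 0, 0))),
               "non-finite")
  expect_error(apply_calibration(rec, fit_calibration(sphere_points(3))),
               "converge")
})

test_that("fitting never increases the post-calibration error", {
  for (s in 1:5) {
    set.seed(100 + s)
    gain <- runif(3, 0.97, 1.03); offset <- runif(3, -0.05, 0.05)
    measured <- sweep(sweep(sphere_points(300, noise_mg = 3), 2, gain, `*`),
                      2, offset, `+`)
    m <- fit_calibration(measured)
    expect_lte(calibration_error(measured, m),
               calibration_error(measured) + 1e-12)
  }
})

test_that("median offset-recovery error stays below 5 mg across simulations", {
  err <- numeric(20)
  for (s in 1:20) {
    set.seed(200 + s)
    gain <- runif(3, 0.97, 1.03); offset <- runif(3, -0.05, 0.05)
    measured <- sweep(sweep(sphere_points(250, noise_mg = 3), 2, gain, `*`),
                      2, offset, `+`)
    m <- fit_calibration(measured)
    err[s] <- max(abs(m$offset_g - (-offset / gain)))
  }
  expect_lt(median(err), 0.005)
})

test_that("re-fitting an already-calibrated recording is idempotent", {
  sensor <- sensor_spec(noise_sd_mg = 3, offset_g = c(0.03, -0.02, 0.015),
                        gain = c(1.02, 0.985, 1.005))
  sim <- generate_freeliving_recording(2, sensor, seed = 21)
  pts <- find_stationary_windows(sim$recording)
  m <- fit_calibration(pts)
  expect_true(m$converged)
  cal <- apply_calibration(sim$recording, m)
  m2 <- fit_calibration(find_stationary_windows(cal))
  expect_lt(max(abs(m2$gain - 1)), 0.002)
  expect_lt(max(abs(m2$offset_g)), 0.002)
})
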