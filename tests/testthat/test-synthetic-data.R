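test_that("ideal sensor and motionless postures give unit gravity and zero ENMO", {
  lab <- generate_lab_recording(lab_protocol_script(),
                                amp = zero_amplitude_model(),
                                sensor = sensor_spec(noise_sd_mg = 0),
                                seed = 3)
  mag <- sample_magnitude(lab$recording)
  expect_lt(max(abs(mag - 1)), 1e-9)
  expect_equal(max(enmo_epochs(lab$recording)), 0)
})

test_that("the lab protocol spans 70 minutes and yields 840 five-second epochs", {
  script <- lab_protocol_script()
  expect_equal(as.numeric(script$end[nrow(script)]) -
                 as.numeric(script$start[1]), 70 * 60)
  lab <- generate_lab_recording(script, seed = 1)
  expect_equal(nrow(epoch_series(lab$recording)), 840)
  # 11 five-minute activities, one two-minute activity
  scored <- script[!is.na(script$code), ]
  expect_equal(nrow(scored), 12L)
  expect_equal(as.numeric(scored$end - scored$start, units = "secs"),
               c(rep(300, 11), 120))
})

test_that("a simulated lab cohort reproduces the target activity amplitudes", {
  script <- lab_protocol_script()
  walking_mad <- sed_mad <- numeric(35)
  sed_all <- NULL
  for (p in 1:35) {
    lab <- generate_lab_recording(script, seed = 5000 + p)
    am <- activity_means(epoch_series(lab$recording), lab$script,
                         participant_id = p)
    walking_mad[p] <- am$mean_mad_mg[am$activity_code == 8]
    sed_all <- c(sed_all, am$mean_mad_mg[am$activity_code <= 6])
  }
  # self-paced walking MAD: cohort median within 10% of the 316.3 mg target
  expect_lt(abs(median(walking_mad) - 316.3) / 316.3, 0.10)
  # pooled sedentary MAD medians sit near the 4.0 mg class target
  expect_lt(abs(median(sed_all) - 4.0), 1.4)
})

test_that("raw CSV round trip preserves samples and start time", {
  set.seed(42)
  rec <- raw_recording(t_origin + 0.05, 20,
                       matrix(rnorm(3 * 1200, 0, 0.5), ncol = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(rec, path)
  expect_equal(length(readLines(path)), 1201L)  # header + 60 s at 20 Hz
  back <- read_raw_csv(path)
  expect_equal(as.numeric(back$start_time), as.numeric(rec$start_time))
  expect_equal(back$sample_rate_hz, 20)
  expect_lt(max(abs(back$data - rec$data)), 1e-6)
})

test_that("malformed raw CSVs are rejected with a line number", {
  rec <- raw_recording(t_origin, 20, matrix(0.5, nrow = 40, ncol = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(rec, path)
  lines <- readLines(path)
  swapped <- lines; swapped[c(5, 6)] <- lines[c(6, 5)]
  writeLines(swapped, path)
  expect_error(read_raw_csv(path), "line")
  writeLines(c("a,b,c", lines[-1]), path)
  expect_error(read_raw_csv(path), "header")
})

test_that("events round-trip through CSV and invalid scripts are rejected", {
  sim <- small_freeliving()
  path <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(sim$events, path)
  back <- read_events_csv(path)
  expect_equal(as.numeric(back$start), as.numeric(sim$events$start))
  expect_equal(back$code, sim$events$code)

  bad <- data.frame(label = c("a", "b"), code = c(1L, 2L),
                    start = t_origin + c(0, 50), end = t_origin + c(100, 150))
  expect_error(activity_script(bad), "overlap")
  script <- lab_protocol_script()
  amp <- default_amplitude_model()
  expect_error(generate_lab_recording(script, amp[amp$label != "walking", ]),
               "walking")
  expect_error(generate_freeliving_recording(0), "days")
})

test_that("seeded generation is reproducible and seeds differ", {
  a <- generate_freeliving_recording(1, seed = 11)
  b <- generate_freeliving_recording(1, seed = 11)
  c <- generate_freeliving_recording(1, seed = 12)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$events, b$events)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("inverting the sensor distortion recovers the undistorted signal", {
  gain <- c(1.03, 0.97, 1.01); offset <- c(0.04, -0.02, 0.01)
  clean <- generate_lab_recording(lab_protocol_script(),
                                  sensor = sensor_spec(noise_sd_mg = 0),
                                  seed = 9)$recording
  dirty <- generate_lab_recording(lab_protocol_script(),
                                  sensor = sensor_spec(noise_sd_mg = 0,
                                                       offset_g = offset,
                                                       gain = gain),
                                  seed = 9)$recording
  inv <- list(gain = 1 / gain, offset_g = -offset / gain, converged = TRUE)
  undone <- apply_calibration(dirty, inv)
  expect_lt(max(abs(undone$data - clean$data)), 1e-12)
})

test_that("emitted events tile the recording and preserve scripted sedentary time", {
  sim <- small_freeliving()
  ev <- sim$events
  dur <- recording_duration(sim$recording)
  expect_equal(sum(as.numeric(ev$end) - as.numeric(ev$start)), dur)
  # contiguous, ordered coverage
  expect_equal(as.numeric(ev$start[-1]), as.numeric(ev$end[-nrow(ev)]))
  expect_true(all(ev$code %in% c(0L, 1L, 2L, 9L)))
})

test_that("a fully sedentary day with an 8-h bed window yields 960 criterion minutes", {
  bp <- behaviour_params(bed_start_jitter_min = 0, bed_duration_min = 480,
                         bed_duration_sd_min = 0, sed_fraction_mean = 1,
                         sed_fraction_sd = 0, sed_fraction_day_sd = 0)
  sim <- generate_freeliving_recording(2, behaviour = bp, seed = 5)
  sleep <- build_sleep_log(sim$events)
  expect_equal(criterion_sedentary(sim$events, sleep, "2024-03-05"), 960)
})

test_that("sensor and behaviour configuration files are parsed", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("sensor:", "  sample_rate_hz: 20", "  noise_sd_mg: 5",
               "behaviour:", "  sed_fraction_mean: 0.6"), path)
  cfg <- read_config(path)
  expect_s3_class(cfg$sensor, "sensor_spec")
  expect_equal(cfg$sensor$noise_sd_mg, 5)
  expect_equal(cfg$behaviour$sed_fraction_mean, 0.6)
})
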