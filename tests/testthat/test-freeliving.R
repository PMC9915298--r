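day_series <- function(n_days, wear = "worn", offset_epochs = 0,
                       drop_tail = 0) {
  n <- n_days * 17280 - offset_epochs - drop_tail
  make_epoch_series(rep(1, n), wear = wear,
                    start = t_origin + offset_epochs * 5)
}

test_that("valid days require complete midnight-to-midnight coverage", {
  # continuous 5-day midnight-aligned series: 5 valid days
  expect_length(valid_days(day_series(5)), 5L)
  # recording starting and ending mid-day spans 8 calendar days: the two
  # partial boundary days are dropped, leaving 6 (and never more than 7)
  es <- day_series(8, offset_epochs = 7000, drop_tail = 5000)
  vd <- valid_days(es)
  expect_length(vd, 6L)
  expect_lte(length(vd), 7L)
  expect_false(as.Date("2024-03-04") %in% vd)
  expect_false(as.Date("2024-03-11") %in% vd)
  # an unimputable epoch invalidates its day
  es2 <- day_series(3)
  es2$wear[17280 + 50] <- "nonwear"
  expect_equal(as.character(valid_days(es2)),
               c("2024-03-04", "2024-03-06"))
})

test_that("criterion sedentary minutes respect day, bed and event boundaries", {
  d <- as.numeric(t_origin)
  events <- posture_events(data.frame(
    start = as.POSIXct(d + c(0, 7 * 3600, 12 * 3600, 22 * 3600),
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(d + c(7 * 3600, 12 * 3600, 22 * 3600, 24 * 3600),
                     origin = "1970-01-01", tz = "UTC"),
    code = c(9L, 1L, 0L, 9L)))
  sleep <- build_sleep_log(events)
  # sedentary bout 12:00-22:00 entirely within waking time
  expect_equal(criterion_sedentary(events, sleep, "2024-03-04"), 600)
  # a bout straddling bed start is clipped at the bed boundary
  ev2 <- posture_events(data.frame(
    start = as.POSIXct(d + c(0, 7 * 3600, 21 * 3600),
                       origin = "1970-01-01", tz = "UTC"),
    end = as.POSIXct(d + c(7 * 3600, 21 * 3600, 24 * 3600),
                     origin = "1970-01-01", tz = "UTC"),
    code = c(9L, 1L, 0L)))
  sl2 <- data.frame(bed_start = as.POSIXct(d + 22 * 3600,
                                           origin = "1970-01-01", tz = "UTC"),
                    bed_end = as.POSIXct(d + 30 * 3600,
                                         origin = "1970-01-01", tz = "UTC"))
  expect_equal(criterion_sedentary(ev2, sl2, "2024-03-04"), 60)
  # no sleep record overlapping the day: rejected
  expect_error(criterion_sedentary(events, sleep, "2024-03-10"), "sleep")
})

test_that("estimated sedentary counts waking epochs below the cut-point", {
  es <- make_epoch_series(c(5, 10, 40, 3, 50, 8, 90, 2, 60, 7, 45, 1))
  sleep <- data.frame(bed_start = t_origin + 3600,
                      bed_end = t_origin + 7200)  # elsewhere in the day
  got <- estimated_sedentary(es, 30, "enmo", sleep, "2024-03-04")
  expect_equal(got, 7 * 5 / 60)  # values 5,10,3,8,2,7,1 below 30 mg
  expect_equal(estimated_sedentary(es, 30, "mad", sleep, "2024-03-04"),
               7 * 5 / 60)
})

test_that("estimates are monotone in the cut-point and conserve waking epochs", {
  set.seed(61)
  es <- make_epoch_series(exp(rnorm(17280, 2, 1.5)))
  sleep <- data.frame(bed_start = t_origin + 23 * 3600,
                      bed_end = t_origin + 31 * 3600)
  cuts <- c(1, 5, 20, 30.1, 100, 1000)
  est <- vapply(cuts, function(ct)
    estimated_sedentary(es, ct, "enmo", sleep, "2024-03-04"), 0)
  expect_true(all(diff(est) >= 0))
  # sedentary + non-sedentary waking epochs = waking epochs
  waking_min <- 23 * 60
  for (ct in cuts) {
    sed <- estimated_sedentary(es, ct, "enmo", sleep, "2024-03-04")
    nonsed_epochs <- sum(as.numeric(es$time) <
                           as.numeric(t_origin) + 23 * 3600 &
                           es$enmo_mg >= ct)
    expect_equal(sed + nonsed_epochs * 5 / 60, waking_min)
  }
})

test_that("the sleep log reproduces the generator's in-bed intervals", {
  bp <- behaviour_params(bed_start_jitter_min = 0, bed_duration_min = 480,
                         bed_duration_sd_min = 0)
  sim <- generate_freeliving_recording(2, behaviour = bp, seed = 8)
  sleep <- build_sleep_log(sim$events)
  bed <- sim$events[sim$events$code == 9L, ]
  expect_equal(as.numeric(sleep$bed_start), as.numeric(bed$start))
  expect_equal(as.numeric(sleep$bed_end), as.numeric(bed$end))
  # fixed 23:00 bed start shows up mid-recording
  expect_true(any(format(sleep$bed_start, "%H:%M") == "23:00"))
})

test_that("a perfectly separable world gives exact estimate-criterion equality", {
  amp <- data.frame(
    class = c("sed", "standing", "light", "stepping", "in_bed", "nonwear"),
    posture = c("reclined", "upright", "upright", "upright", "reclined",
                "flat"),
    mad_med = c(0, 0, 300, 300, 0, 0),
    enmo_med = c(0, 0, 300, 300, 0, 0),
    gamma = 1, s_bout = 0, s_epoch = 0)
  bp <- behaviour_params(upright_mix = c(standing = 0, light = 0.7,
                                         stepping = 0.3),
                         amplitudes = amp)
  sim <- generate_freeliving_recording(2, sensor_spec(noise_sd_mg = 0),
                                       behaviour = bp, seed = 71)
  es <- epoch_series(sim$recording)
  sleep <- build_sleep_log(sim$events)
  for (d in as.list(valid_days(es))) {
    crit <- criterion_sedentary(sim$events, sleep, d)
    for (m in c("mad", "enmo")) {
      expect_equal(estimated_sedentary(es, 30, m, sleep, d), crit)
    }
  }
})

test_that("daily summaries pair criterion and estimates over one waking window", {
  sim <- small_freeliving()
  nw <- detect_nonwear(sim$recording)
  es <- impute_nonwear(epoch_series(sim$recording, nonwear = nw))
  ds <- daily_summaries(es, sim$events,
                        c(enmo = 26.4, mad = 30.1, enmo_s = 21.9),
                        participant_id = 42)
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$participant_id, 42)
  expect_true(all(ds$criterion_sed_min <= ds$waking_min))
  expect_true(all(ds$est_mad_min <= ds$waking_min))
  # estimates from a larger threshold dominate a smaller one of same metric
  expect_gte(ds$est_enmo_min, ds$est_enmo_s_min)
})
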