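.freeliving_amplitudes <- function() {
  data.frame(
    class = c("sed", "standing", "light", "stepping", "in_bed", "nonwear"),
    posture = c("reclined", "upright", "upright", "upright", "reclined", "flat"),
    mad_med = c(4.0, 4.5, 70, 316.3, 1.5, 0),
    enmo_med = c(5.1, 5.6, 43.4, 240.5, 2.0, 0),
    gamma = c(0.63, 2.0, 1.0, 1.0, 1.0, 1.0),
    s_bout = c(0.40, 0.30, 0.30, 0.25, 0.30, 0),
    s_epoch = c(1.13, 0.74, 0.40, 0.25, 0.40, 0))
}

#' Free-living behaviour parameters
#'
#' Defaults describe a young-adult cohort wearing the device continuously:
#' a nightly time-in-bed window of about 8.1 h starting around 23:00, a
#' waking sedentary fraction of 0.575 (so criterion sedentary time averages
#' roughly 550 min/day), sedentary bouts of median 15 min and upright bouts
#' of median 8 min (both capped at 40 min so that any one-hour stretch
#' contains a posture transition), and upright time split between quiet
#' standing, standing with light movement, and stepping. Epoch-level
#' amplitude targets per behaviour class are given by `amplitudes` (mg);
#' within-bout epoch variability is deliberately heavy-tailed for sedentary
#' behaviour (fidgeting) and light for steady ambulation.
#'
#' @param bed_start_hour clock hour of the nominal bed start.
#' @param bed_start_jitter_min SD (minutes) of the nightly bed-start jitter.
#' @param bed_duration_min,bed_duration_sd_min mean and SD (minutes) of
#'   nightly time in bed.
#' @param sed_fraction_mean,sed_fraction_sd,sed_fraction_day_sd mean waking
#'   sedentary fraction, its between-participant SD, and the day-to-day SD.
#' @param sed_bout_meanlog,sed_bout_sdlog,sed_bout_range_min lognormal
#'   parameters (minutes) and clamp range for sedentary bout lengths.
#' @param upright_bout_meanlog,upright_bout_sdlog,upright_bout_range_min
#'   the same for upright bouts.
#' @param upright_mix named fractions of upright time in classes
#'   `standing` (quiet), `light` (standing with light movement), `stepping`.
#' @param bed_turn_range_min range (minutes) of intervals between posture
#'   turns while in bed.
#' @param amplitudes per-class amplitude table (see
#'   `sedcut:::.freeliving_amplitudes`).
#' @param nonwear optional data.frame (`day`, `start_hour`, `end_hour`)
#'   of scripted non-wear intervals: the device lies flat and motionless.
#' @return list of class `behaviour_params`.
#' @export
behaviour_params <- function(bed_start_hour = 23,
                             bed_start_jitter_min = 20,
                             bed_duration_min = 486,
                             bed_duration_sd_min = 25,
                             sed_fraction_mean = 0.575,
                             sed_fraction_sd = 0.089,
                             sed_fraction_day_sd = 0.04,
                             sed_bout_meanlog = log(15),
                             sed_bout_sdlog = 0.7,
                             sed_bout_range_min = c(2, 40),
                             upright_bout_meanlog = log(8),
                             upright_bout_sdlog = 0.6,
                             upright_bout_range_min = c(1, 40),
                             upright_mix = c(standing = 0.04, light = 0.72,
                                             stepping = 0.24),
                             bed_turn_range_min = c(15, 40),
                             amplitudes = .freeliving_amplitudes(),
                             nonwear = NULL) {
  upright_mix <- upright_mix / sum(upright_mix)
  structure(as.list(environment()), class = "behaviour_params")
}

.q5 <- function(x) round(x / 5) * 5  # quantize to the 5-s epoch grid

# fill one waking interval [a, b) (seconds) with alternating sedentary /
# upright bouts targeting sedentary fraction f; returns data.frame with
# class, start, end
.fill_waking <- function(a, b, f, bp) {
  len <- b - a
  if (len <= 0) return(NULL)
  if (f >= 0.999) {
    return(data.frame(class = "sed", start = a, end = b))
  }
  m_sed <- .capped_ln_mean(bp$sed_bout_meanlog, bp$sed_bout_sdlog,
                           bp$sed_bout_range_min[1], bp$sed_bout_range_min[2])
  m_up <- .capped_ln_mean(bp$upright_bout_meanlog, bp$upright_bout_sdlog,
                          bp$upright_bout_range_min[1],
                          bp$upright_bout_range_min[2])
  r_up <- if (f <= 0.001) Inf else m_sed * (1 - f) / (m_up * f)
  cls <- character(0); st <- numeric(0); en <- numeric(0)
  t <- a
  sed_turn <- runif(1) < f
  while (t < b - 1e-9) {
    if (sed_turn && f > 0.001) {
      d <- 60 * .rln_capped(1, bp$sed_bout_meanlog, bp$sed_bout_sdlog,
                            bp$sed_bout_range_min[1], bp$sed_bout_range_min[2])
      cl <- "sed"
    } else {
      d0 <- .rln_capped(1, bp$upright_bout_meanlog, bp$upright_bout_sdlog,
                        bp$upright_bout_range_min[1],
                        bp$upright_bout_range_min[2])
      # scale upright bouts so the interval's expected sedentary fraction is
      # f, but keep the per-bout cap (posture transition at least hourly)
      d <- 60 * min(d0 * min(r_up, 1e6), bp$upright_bout_range_min[2])
      cl <- sample(c("standing", "light", "stepping"), 1,
                   prob = bp$upright_mix)
    }
    d <- max(.q5(d), 5)
    en_i <- min(t + d, b)
    cls <- c(cls, cl); st <- c(st, t); en <- c(en, en_i)
    t <- en_i
    sed_turn <- !sed_turn
  }
  data.frame(class = cls, start = st, end = en)
}

#' Generate a multi-day free-living recording with posture ground truth
#'
#' Simulates continuous 24 h/day wear across `days` calendar days: nightly
#' time-in-bed intervals (lying, with posture turns), and waking time filled
#' with alternating sedentary and upright bouts whose classes, lengths and
#' movement amplitudes follow `behaviour`. Returns the raw signal together
#' with the ground-truth posture event series (codes 0 sedentary, 1 standing,
#' 2 stepping, 9 in bed) that serves as the criterion measure; the realised
#' per-day criterion sedentary minutes are recoverable exactly from the
#' events. Generation is reproducible per seed.
#'
#' @param days number of calendar days spanned (>= 1).
#' @param sensor a [sensor_spec()].
#' @param behaviour a [behaviour_params()].
#' @param seed integer RNG seed.
#' @param start_date first calendar day (midnight UTC anchors the recording
#'   unless offsets are given).
#' @param start_offset_s seconds after midnight of day 1 at which the
#'   recording starts (use > 0 for a partial first day).
#' @param end_offset_s seconds before midnight at the end of the last day at
#'   which the recording stops.
#' @return list with elements `recording` ([raw_recording()]) and `events`
#'   ([posture_events()]).
#' @export
generate_freeliving_recording <- function(days, sensor = sensor_spec(),
                                          behaviour = behaviour_params(),
                                          seed = 1L,
                                          start_date = "2024-03-04",
                                          start_offset_s = 0,
                                          end_offset_s = 0) {
  if (days < 1) stop("`days` must be >= 1")
  bp <- behaviour
  set.seed(as.integer(seed))
  day0 <- as.numeric(as.POSIXct(paste(start_date, "00:00:00"), tz = .tz))
  t0 <- .q5(day0 + start_offset_s)
  t1 <- .q5(day0 + days * 86400 - end_offset_s)
  if (t1 <= t0) stop("empty recording window")

  # nightly in-bed intervals (night d starts on calendar day d)
  beds <- NULL
  for (d in seq(-1L, days - 1L)) {
    bs <- day0 + d * 86400 + bp$bed_start_hour * 3600 +
      rnorm(1, 0, bp$bed_start_jitter_min * 60)
    be <- bs + max(rnorm(1, bp$bed_duration_min * 60,
                         bp$bed_duration_sd_min * 60), 3600)
    bs <- max(.q5(bs), t0); be <- min(.q5(be), t1)
    if (be - bs >= 5) beds <- rbind(beds, c(bs, be))
  }

  # waking complement
  bounds <- c(t0, as.vector(t(beds)), t1)
  segs_list <- list(); ev_list <- list()
  f_p <- min(max(rnorm(1, bp$sed_fraction_mean, bp$sed_fraction_sd),
                 0.02), 1)
  amp <- bp$amplitudes
  az <- runif(1, 0, 2 * pi)
  add_block <- function(class, a, b) {
    i <- match(class, amp$class)
    if (amp$posture[i] == "upright") {
      u <- .orient_upright()
    } else if (amp$posture[i] == "flat") {
      u <- c(0, 0, 1)
    } else {
      az <<- .next_azimuth(az)
      # in bed the legs bend and roll: the thigh strays much further from
      # horizontal than it does in daytime sitting/lying
      u <- .orient_reclined(az, if (class == "in_bed") 40 else 20)
    }
    data.frame(start = a, dur_s = b - a, ux = u[1], uy = u[2], uz = u[3],
               mad_med = amp$mad_med[i], enmo_med = amp$enmo_med[i],
               gamma = amp$gamma[i], s_epoch = amp$s_epoch[i],
               lm_bout = rnorm(1, 0, amp$s_bout[i]), type = class,
               stringsAsFactors = FALSE)
  }

  n_int <- nrow(beds) + 1L
  for (k in seq_len(n_int)) {
    a <- bounds[2 * k - 1]; b <- bounds[2 * k]
    if (b - a < 5) next
    f_d <- min(max(f_p + rnorm(1, 0, bp$sed_fraction_day_sd), 0.05), 1)
    bouts <- .fill_waking(a, b, f_d, bp)
    if (is.null(bouts)) next
    for (j in seq_len(nrow(bouts))) {
      segs_list[[length(segs_list) + 1L]] <-
        add_block(bouts$class[j], bouts$start[j], bouts$end[j])
    }
    code <- c(sed = 0L, standing = 1L, light = 1L, stepping = 2L)[bouts$class]
    ev_list[[length(ev_list) + 1L]] <-
      data.frame(start = bouts$start, end = bouts$end, code = code)
  }
  # bed intervals: one code-9 event each; posture turns inside
  for (k in seq_len(nrow(beds))) {
    a <- beds[k, 1]; b <- beds[k, 2]
    t <- a
    while (t < b) {
      e <- min(.q5(t + runif(1, bp$bed_turn_range_min[1],
                             bp$bed_turn_range_min[2]) * 60), b)
      if (e - t < 5) e <- b
      segs_list[[length(segs_list) + 1L]] <- add_block("in_bed", t, e)
      t <- e
    }
    ev_list[[length(ev_list) + 1L]] <- data.frame(start = a, end = b,
                                                  code = 9L)
  }

  segs <- do.call(rbind, segs_list)
  segs <- segs[order(segs$start), , drop = FALSE]
  if (!is.null(bp$nonwear)) segs <- .apply_nonwear(segs, bp$nonwear, day0, amp)
  ev <- do.call(rbind, ev_list)
  ev <- ev[order(ev$start), , drop = FALSE]
  events <- posture_events(data.frame(
    start = as.POSIXct(ev$start, origin = "1970-01-01", tz = .tz),
    end = as.POSIXct(ev$end, origin = "1970-01-01", tz = .tz),
    code = ev$code))

  rec <- .synth_recording(segs, as.POSIXct(t0, origin = "1970-01-01",
                                           tz = .tz), sensor)
  list(recording = rec, events = events)
}

# replace the portions of the segment table covered by scripted non-wear with
# a flat, motionless device; ground-truth behaviour events are left untouched
.apply_nonwear <- function(segs, nonwear, day0, amp) {
  i_nw <- match("nonwear", amp$class)
  for (r in seq_len(nrow(nonwear))) {
    a <- .q5(day0 + (nonwear$day[r] - 1) * 86400 + nonwear$start_hour[r] * 3600)
    b <- .q5(day0 + (nonwear$day[r] - 1) * 86400 + nonwear$end_hour[r] * 3600)
    out <- list()
    for (j in seq_len(nrow(segs))) {
      s <- segs[j, ]
      s_end <- s$start + s$dur_s
      if (s_end <= a || s$start >= b) { out[[length(out) + 1L]] <- s; next }
      if (s$start < a) {
        pre <- s; pre$dur_s <- a - s$start
        out[[length(out) + 1L]] <- pre
      }
      nw <- s
      nw$start <- max(s$start, a); nw$dur_s <- min(s_end, b) - nw$start
      nw$ux <- 0; nw$uy <- 0; nw$uz <- 1
      nw$mad_med <- 0; nw$enmo_med <- 0; nw$gamma <- 1
      nw$s_epoch <- 0; nw$lm_bout <- 0; nw$type <- "nonwear"
      out[[length(out) + 1L]] <- nw
      if (s_end > b) {
        post <- s; post$start <- b; post$dur_s <- s_end - b
        out[[length(out) + 1L]] <- post
      }
    }
    segs <- do.call(rbind, out)
  }
  segs[order(segs$start), , drop = FALSE]
}
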