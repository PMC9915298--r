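#' Build a sleep log from posture events
#'
#' Extracts the ground-truth time-in-bed intervals (code 9) into a sleep
#' log. The same log is used by both the criterion and the cut-point
#' estimation paths, so sleep is excluded over identical timeframes.
#'
#' @param events a [posture_events()] series.
#' @return data.frame of class `sleep_log` with columns `bed_start`,
#'   `bed_end`.
#' @export
build_sleep_log <- function(events) {
  bed <- events[events$code == 9L, c("start", "end")]
  names(bed) <- c("bed_start", "bed_end")
  rownames(bed) <- NULL
  class(bed) <- c("sleep_log", "data.frame")
  bed
}

# waking sub-intervals of calendar day `date`: the day minus every in-bed
# interval overlapping it; returned as a 2-column matrix of numeric seconds
.waking_intervals <- function(sleep, date) {
  d0 <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = .tz))
  d1 <- d0 + 86400
  lo <- pmax(as.numeric(sleep$bed_start), d0)
  hi <- pmin(as.numeric(sleep$bed_end), d1)
  keep <- hi > lo
  if (!any(keep)) return(matrix(c(d0, d1), ncol = 2L))
  beds <- cbind(lo[keep], hi[keep])
  beds <- beds[order(beds[, 1L]), , drop = FALSE]
  starts <- c(d0, beds[, 2L])
  ends <- c(beds[, 1L], d1)
  ok <- ends > starts
  cbind(starts[ok], ends[ok])
}

.has_sleep_record <- function(sleep, date) {
  d0 <- as.numeric(as.POSIXct(paste(date, "00:00:00"), tz = .tz))
  any(as.numeric(sleep$bed_end) > d0 &
        as.numeric(sleep$bed_start) < d0 + 86400)
}

#' Valid wear days of an epoch series
#'
#' A calendar day (midnight-to-midnight) is valid when the series covers all
#' of its epochs and none of them is unimputable non-wear; partial first and
#' last days are excluded by the coverage requirement. Imputed epochs count
#' as valid coverage.
#'
#' @param series an [epoch_series()] (after [impute_nonwear()] if non-wear
#'   detection was run).
#' @return `Date` vector of valid days (possibly empty).
#' @export
valid_days <- function(series) {
  epoch_s <- attr(series, "epoch_s") %||% 5
  need <- 86400 / epoch_s
  day <- as.Date(floor(as.numeric(series$time) / 86400),
                 origin = "1970-01-01")
  cov <- tapply(rep(1L, nrow(series)), day, sum)
  bad <- tapply(series$wear == "nonwear", day, any)
  as.Date(names(cov)[cov == need & !bad])
}

#' Criterion sedentary minutes for one day
#'
#' Sums the durations of sedentary-coded (code 0) posture events within the
#' calendar day's waking window (the day minus every time-in-bed interval of
#' the sleep log overlapping it); events are clipped at day and bed
#' boundaries. This is the criterion measure the cut-point estimates are
#' compared against.
#'
#' @param events a [posture_events()] series.
#' @param sleep a sleep log from [build_sleep_log()].
#' @param date `Date` (or coercible) calendar day.
#' @return minutes of criterion sedentary time.
#' @export
criterion_sedentary <- function(events, sleep, date) {
  date <- as.Date(date)
  if (!.has_sleep_record(sleep, date)) {
    stop("no sleep record overlapping ", format(date))
  }
  wk <- .waking_intervals(sleep, date)
  sed <- events[events$code == 0L, , drop = FALSE]
  if (!nrow(sed)) return(0)
  s <- as.numeric(sed$start); e <- as.numeric(sed$end)
  tot <- 0
  for (k in seq_len(nrow(wk))) {
    tot <- tot + sum(pmax(pmin(e, wk[k, 2L]) - pmax(s, wk[k, 1L]), 0))
  }
  tot / 60
}

#' Cut-point sedentary minutes for one day
#'
#' Counts waking epochs whose metric value is strictly below the cut-point
#' and converts the count to minutes. An epoch is waking iff its start lies
#' inside the day's waking window (half-open convention at bed boundaries) —
#' the same window used by [criterion_sedentary()].
#'
#' @param series an imputed [epoch_series()].
#' @param cutpoint_mg acceleration threshold in mg.
#' @param metric `"mad"` or `"enmo"`.
#' @param sleep sleep log from [build_sleep_log()].
#' @param date calendar day.
#' @return minutes classified sedentary.
#' @export
estimated_sedentary <- function(series, cutpoint_mg,
                                metric = c("mad", "enmo"), sleep, date) {
  metric <- match.arg(metric)
  date <- as.Date(date)
  if (!.has_sleep_record(sleep, date)) {
    stop("no sleep record overlapping ", format(date))
  }
  epoch_s <- attr(series, "epoch_s") %||% 5
  wk <- .waking_intervals(sleep, date)
  t0 <- as.numeric(series$time)
  waking <- rep(FALSE, length(t0))
  for (k in seq_len(nrow(wk))) {
    waking <- waking | (t0 >= wk[k, 1L] & t0 < wk[k, 2L])
  }
  v <- if (metric == "mad") series$mad_mg else series$enmo_mg
  sum(waking & v < cutpoint_mg) * epoch_s / 60
}

#' Daily criterion and cut-point summaries
#'
#' For every valid day of the series that has sleep-log coverage, computes
#' waking minutes, criterion sedentary minutes from the posture events, and
#' one cut-point estimate per entry of `cutpoints` — all over the identical
#' waking window.
#'
#' @param series an imputed [epoch_series()].
#' @param events a [posture_events()] series (criterion ground truth).
#' @param cutpoints named numeric vector of thresholds in mg; each name must
#'   be `"enmo"` or `"mad"`, optionally suffixed (e.g. `enmo_s = 21.9`), and
#'   selects the metric by its prefix.
#' @param sleep sleep log; defaults to [build_sleep_log()] of `events`.
#' @param participant_id optional id column value.
#' @return data.frame with one row per valid day: `participant_id`, `date`,
#'   `waking_min`, `criterion_sed_min` and `est_<name>_min` columns.
#' @export
daily_summaries <- function(series, events,
                            cutpoints = c(enmo = 26.4, mad = 30.1),
                            sleep = build_sleep_log(events),
                            participant_id = NA) {
  stopifnot(!is.null(names(cutpoints)))
  days <- valid_days(series)
  days <- days[vapply(days, function(d) .has_sleep_record(sleep, d), TRUE)]
  if (!length(days)) return(NULL)
  rows <- lapply(days, function(d) {
    wk <- .waking_intervals(sleep, d)
    row <- data.frame(participant_id = participant_id, date = d,
                      waking_min = sum(wk[, 2L] - wk[, 1L]) / 60,
                      criterion_sed_min = criterion_sedentary(events, sleep, d))
    for (nm in names(cutpoints)) {
      metric <- if (startsWith(nm, "mad")) "mad" else "enmo"
      row[[paste0("est_", nm, "_min")]] <-
        estimated_sedentary(series, cutpoints[[nm]], metric, sleep, d)
    }
    row
  })
  do.call(rbind, rows)
}
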