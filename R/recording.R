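#' Tri-axial raw acceleration recording
#'
#' Container for a uniformly sampled tri-axial acceleration signal in
#' gravitational units (g). This is the common currency of the package:
#' the synthetic generators emit it, the calibration and epoch-metric
#' functions consume it.
#'
#' @param start_time `POSIXct` timestamp of the first sample (UTC).
#' @param sample_rate_hz sampling frequency in Hz (e.g. 20).
#' @param data numeric matrix with columns `x`, `y`, `z`, one row per sample,
#'   values in g.
#'
#' @return An object of class `raw_recording`: a list with elements
#'   `start_time`, `sample_rate_hz` and `data`.
#' @export
raw_recording <- function(start_time, sample_rate_hz, data) {
  if (!inherits(start_time, "POSIXct")) {
    start_time <- as.POSIXct(start_time, tz = .tz)
  }
  attr(start_time, "tzone") <- .tz
  stopifnot(is.numeric(sample_rate_hz), length(sample_rate_hz) == 1L,
            sample_rate_hz > 0)
  data <- as.matrix(data)
  if (ncol(data) != 3L) stop("`data` must have three columns (x, y, z)")
  if (!all(is.finite(data))) stop("`data` must be finite")
  colnames(data) <- c("x", "y", "z")
  structure(list(start_time = start_time,
                 sample_rate_hz = sample_rate_hz,
                 data = data),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$sample_rate_hz
  cat(sprintf("<raw_recording> %d samples @ %g Hz (%.1f min) from %s UTC\n",
              nrow(x$data), x$sample_rate_hz, dur / 60,
              format(x$start_time, "%Y-%m-%d %H:%M:%OS2")))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [raw_recording()].
#' @return numeric seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$sample_rate_hz

#' Per-sample vector magnitude
#' @param rec a [raw_recording()].
#' @return numeric vector of Euclidean norms, in g.
#' @export
sample_magnitude <- function(rec) {
  sqrt(rec$data[, 1]^2 + rec$data[, 2]^2 + rec$data[, 3]^2)
}

# format.POSIXct truncates fractional seconds; build the millisecond part
# from rounded integer milliseconds so written timestamps are exact
.fmt_time <- function(t) {
  ms <- round(as.numeric(t) * 1000)
  sec <- as.POSIXct(floor(ms / 1000), origin = "1970-01-01", tz = .tz)
  sprintf("%s.%03d", format(sec, "%Y-%m-%dT%H:%M:%S", tz = .tz), ms %% 1000)
}

.parse_time <- function(s) {
  as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%OS", tz = .tz)
}

#' Write / read a raw recording as CSV
#'
#' The on-disk dialect is a plain header line `time,x,y,z` followed by one
#' row per sample: an ISO-8601 timestamp (millisecond precision) and the
#' three axis values in g. A round trip preserves sample values to at least
#' six decimal places and the start time exactly.
#'
#' @param rec a [raw_recording()].
#' @param path file path.
#' @return `write_raw_csv()` returns `path` invisibly; `read_raw_csv()`
#'   returns a [raw_recording()].
#' @export
write_raw_csv <- function(rec, path) {
  n <- nrow(rec$data)
  times <- rec$start_time + (seq_len(n) - 1L) / rec$sample_rate_hz
  dt <- data.table(time = .fmt_time(times),
                   x = sprintf("%.7f", rec$data[, 1]),
                   y = sprintf("%.7f", rec$data[, 2]),
                   z = sprintf("%.7f", rec$data[, 3]))
  fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_raw_csv
#' @export
read_raw_csv <- function(path) {
  dt <- suppressWarnings(fread(path, colClasses = "character"))
  need <- c("time", "x", "y", "z")
  if (!all(need %in% names(dt))) {
    stop("malformed header: expected columns time,x,y,z (line 1)")
  }
  tt <- .parse_time(dt$time)
  if (anyNA(tt)) {
    bad <- which(is.na(tt))[1L]
    stop(sprintf("unparsable timestamp at line %d", bad + 1L))
  }
  tnum <- as.numeric(tt)
  if (length(tnum) > 1L) {
    dts <- diff(tnum)
    step <- stats::median(dts)
    if (step <= 0) stop("non-positive median sampling interval")
    bad <- which(dts <= 0 | abs(dts - step) > step * 0.01)
    if (length(bad)) {
      stop(sprintf("non-monotone or non-uniform timestamps at line %d",
                   bad[1L] + 2L))
    }
    rate <- 1 / step
    # strptime fractional seconds carry ~1e-7 s float jitter; snap to an
    # integer rate when that is clearly what the file encodes
    if (abs(rate - round(rate)) < 0.001) rate <- round(rate)
  } else {
    rate <- 1
  }
  xyz <- suppressWarnings(cbind(as.numeric(dt$x), as.numeric(dt$y),
                                as.numeric(dt$z)))
  bad <- which(!is.finite(xyz[, 1L]) | !is.finite(xyz[, 2L]) |
                 !is.finite(xyz[, 3L]))
  if (length(bad)) stop(sprintf("non-numeric sample at line %d", bad[1L] + 1L))
  raw_recording(tt[1L], round(rate, 6), xyz)
}

#' Write / read posture event series as CSV
#'
#' Events are stored as `start,end,code` with ISO-8601 timestamps and the
#' integer codes 0 = sedentary, 1 = standing, 2 = stepping, 9 = in bed.
#'
#' @param events a `posture_events` data.frame (columns `start`, `end`,
#'   `code`), as emitted by [generate_freeliving_recording()].
#' @param path file path.
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` returns a `posture_events` data.frame.
#' @export
write_events_csv <- function(events, path) {
  dt <- data.table(start = .fmt_time(events$start),
                   end = .fmt_time(events$end),
                   code = as.integer(events$code))
  fwrite(dt, path, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  dt <- fread(path, colClasses = list(character = c("start", "end")))
  ev <- data.frame(start = .parse_time(dt$start),
                   end = .parse_time(dt$end),
                   code = as.integer(dt$code))
  posture_events(ev)
}

#' Posture event series (criterion ground truth)
#'
#' @param df data.frame with `POSIXct` columns `start`, `end` and integer
#'   `code` (0 sedentary, 1 standing, 2 stepping, 9 in bed).
#' @return the validated data.frame with class `posture_events`.
#' @export
posture_events <- function(df) {
  stopifnot(all(c("start", "end", "code") %in% names(df)))
  if (any(!df$code %in% c(0L, 1L, 2L, 9L))) stop("unknown posture code")
  if (any(df$end <= df$start)) stop("event end must be after start")
  o <- order(as.numeric(df$start))
  df <- df[o, , drop = FALSE]
  if (nrow(df) > 1L &&
      any(as.numeric(df$start[-1L]) <
          as.numeric(df$end[-nrow(df)]) - 1e-9)) {
    stop("events must be non-overlapping")
  }
  rownames(df) <- NULL
  class(df) <- c("posture_events", "data.frame")
  df
}

#' Read a sensor / behaviour configuration file
#'
#' YAML configuration with optional top-level blocks `sensor` (fields of
#' [sensor_spec()]) and `behaviour` (fields of [behaviour_params()]).
#'
#' @param path YAML file path.
#' @return list with elements `sensor` ([sensor_spec()]) and `behaviour`
#'   ([behaviour_params()]); missing blocks fall back to defaults.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sensor <- do.call(sensor_spec, cfg$sensor %||% list())
  behaviour <- do.call(behaviour_params, cfg$behaviour %||% list())
  list(sensor = sensor, behaviour = behaviour)
}
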