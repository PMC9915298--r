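#' Simulate and process a free-living cohort
#'
#' End-to-end driver used for cut-point evaluation studies: for each
#' participant it simulates a multi-day free-living recording (with a
#' randomly miscalibrated sensor), auto-calibrates it from stationary
#' windows, computes the 5-s epoch series with non-wear detection and
#' same-clock-time imputation, and keeps the ground-truth events and sleep
#' log. `n_invalid` participants are given short recordings that span no
#' complete midnight-to-midnight day, so they carry no valid wear day and
#' are excluded by [cohort_filter()] — mimicking wear-compliance failures.
#'
#' @param n cohort size.
#' @param days full calendar days recorded per compliant participant.
#' @param n_invalid number of participants with no complete 24-h day.
#' @param seed master seed; per-participant sub-seeds are derived from it.
#' @param behaviour a [behaviour_params()].
#' @param noise_sd_mg sensor noise, mg.
#' @param miscalibrate draw per-participant axis offsets (within +/-30 mg)
#'   and gains (0.98-1.02)? If `FALSE` sensors are ideal and calibration is
#'   skipped.
#' @return list of class `freeliving_cohort`; each element has `id`,
#'   `epochs`, `events`, `sleep`, `valid_days`, `post_error_g`,
#'   `calibration`.
#' @export
simulate_freeliving_cohort <- function(n = 38, days = 6, n_invalid = 2,
                                       seed = 1L,
                                       behaviour = behaviour_params(),
                                       noise_sd_mg = 3,
                                       miscalibrate = TRUE) {
  out <- vector("list", n)
  for (p in seq_len(n)) {
    pseed <- (seed * 10007L + 131L * p) %% 2147483647L
    set.seed(pseed)
    sensor <- if (miscalibrate) {
      sensor_spec(noise_sd_mg = noise_sd_mg,
                  offset_g = runif(3, -0.03, 0.03),
                  gain = runif(3, 0.98, 1.02))
    } else {
      sensor_spec(noise_sd_mg = noise_sd_mg)
    }
    invalid <- p > n - n_invalid
    sim <- if (invalid) {
      generate_freeliving_recording(2, sensor, behaviour, seed = pseed + 1L,
                                    start_offset_s = 9 * 3600,
                                    end_offset_s = 9 * 3600)
    } else {
      generate_freeliving_recording(days, sensor, behaviour,
                                    seed = pseed + 1L)
    }
    rec <- sim$recording
    model <- NULL
    post_error <- NA_real_
    if (miscalibrate) {
      pts <- find_stationary_windows(rec, clip_range_g = sensor$dynamic_range_g)
      model <- fit_calibration(pts)
      post_error <- model$post_error_g
      if (model$converged) rec <- apply_calibration(rec, model)
    }
    nw <- detect_nonwear(rec)
    es <- impute_nonwear(epoch_series(rec, nonwear = nw))
    out[[p]] <- list(id = p, epochs = es, events = sim$events,
                     sleep = build_sleep_log(sim$events),
                     valid_days = valid_days(es),
                     post_error_g = post_error, calibration = model)
    rm(rec, sim); gc(FALSE)
  }
  class(out) <- "freeliving_cohort"
  out
}

#' Apply the wear-validity inclusion rule to a cohort
#'
#' Retains participants with at least `min_days` valid 24-h wear day(s) and,
#' when auto-calibration was run, a post-calibration error below
#' `max_post_error_g`.
#'
#' @param cohort a `freeliving_cohort`.
#' @param min_days minimum number of valid days (default 1).
#' @param max_post_error_g file-inclusion criterion, g (default 0.02).
#' @return the filtered `freeliving_cohort`.
#' @export
cohort_filter <- function(cohort, min_days = 1, max_post_error_g = 0.02) {
  keep <- vapply(cohort, function(p) {
    length(p$valid_days) >= min_days &&
      (is.na(p$post_error_g) || p$post_error_g < max_post_error_g)
  }, TRUE)
  out <- cohort[keep]
  class(out) <- "freeliving_cohort"
  out
}

#' Wear accounting across a cohort
#'
#' @param n_days_per_participant integer vector of valid-day counts, one per
#'   retained participant.
#' @return list with `n_participants`, `n_days` (total) and `mean_days`
#'   (valid days per participant, to one decimal as conventionally
#'   reported) plus `sd_days`.
#' @export
wear_accounting <- function(n_days_per_participant) {
  x <- as.numeric(n_days_per_participant)
  list(n_participants = length(x), n_days = sum(x),
       mean_days = round(sum(x) / length(x), 1),
       sd_days = round(sd(x), 1))
}

#' Daily summaries for every participant of a cohort
#'
#' @param cohort a (filtered) `freeliving_cohort`.
#' @param cutpoints named thresholds, see [daily_summaries()].
#' @return data.frame of per-participant-day rows.
#' @export
cohort_daily_summaries <- function(cohort,
                                   cutpoints = c(enmo = 26.4, mad = 30.1)) {
  do.call(rbind, lapply(cohort, function(p) {
    daily_summaries(p$epochs, p$events, cutpoints, p$sleep,
                    participant_id = p$id)
  }))
}

#' Participant-level paired estimates
#'
#' Averages daily values per participant and pairs the criterion with one
#' cut-point estimate — the unit of analysis for the agreement statistics.
#'
#' @param daily output of [cohort_daily_summaries()].
#' @param est_col name of the estimate column (e.g. `"est_mad_min"`).
#' @return data.frame with columns `id`, `criterion`, `comparison`.
#' @export
participant_pairs <- function(daily, est_col) {
  ids <- unique(daily$participant_id)
  data.frame(
    id = ids,
    criterion = vapply(ids, function(i)
      mean(daily$criterion_sed_min[daily$participant_id == i]), 0),
    comparison = vapply(ids, function(i)
      mean(daily[[est_col]][daily$participant_id == i]), 0))
}
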