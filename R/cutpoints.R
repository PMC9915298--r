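#' Per-activity trimmed epoch means
#'
#' Reduces an epoch series to one ENMO and one MAD mean per scored activity
#' bout, using only epochs wholly inside the bout's trimmed interior
#' `[start + trim_s, end - trim_s)`; the first and last 30 s of each
#' activity are excluded by default to avoid transition artefacts. Bouts
#' shorter than `2 * trim_s` are rejected with a warning; bouts with
#' `code = NA` (breaks, lead-in/out) are ignored.
#'
#' @param series an [epoch_series()].
#' @param script an [activity_script()].
#' @param trim_s seconds trimmed from each end of every bout.
#' @param participant_id optional id carried into the output.
#' @return data.frame with columns `participant_id`, `activity_code`,
#'   `label`, `n_epochs`, `mean_enmo_mg`, `mean_mad_mg`.
#' @export
activity_means <- function(series, script, trim_s = 30,
                           participant_id = NA) {
  epoch_s <- attr(series, "epoch_s") %||% 5
  t0 <- as.numeric(series$time)
  out <- list()
  for (i in seq_len(nrow(script))) {
    code <- script$code[i]
    if (is.na(code)) next
    a <- as.numeric(script$start[i]) + trim_s
    b <- as.numeric(script$end[i]) - trim_s
    if (b <= a) {
      warning(sprintf("bout %s shorter than 2*trim_s; skipped",
                      script$label[i]))
      next
    }
    sel <- t0 >= a - 1e-9 & (t0 + epoch_s) <= b + 1e-9
    if (!any(sel)) next
    out[[length(out) + 1L]] <- data.frame(
      participant_id = participant_id, activity_code = as.integer(code),
      label = script$label[i], n_epochs = sum(sel),
      mean_enmo_mg = mean(series$enmo_mg[sel]),
      mean_mad_mg = mean(series$mad_mg[sel]))
  }
  do.call(rbind, out)
}

#' Label activity summaries for cut-point derivation
#'
#' Assigns the binary class used by the ROC analysis. Under
#' `"sed_vs_nonsed"`, the lying and sitting activities (codes 1-6) are the
#' sedentary positives and all upright activities (codes 7-12) the
#' negatives. Under `"sed_vs_passive_standing"` the negatives are reduced to
#' quiet standing (code 7) alone, the variant used to derive the
#' sedentary-vs-standing ENMO cut-point.
#'
#' @param summaries output of [activity_means()] (possibly row-bound over
#'   participants).
#' @param scheme labelling scheme.
#' @return `summaries` filtered to the activities the scheme uses, with a
#'   logical column `sedentary`.
#' @export
label_activities <- function(summaries,
                             scheme = c("sed_vs_nonsed",
                                        "sed_vs_passive_standing")) {
  scheme <- match.arg(scheme)
  code <- summaries$activity_code
  if (any(!code %in% 1:12)) stop("unknown activity code")
  summaries$sedentary <- code <= 6L
  if (scheme == "sed_vs_passive_standing") {
    summaries <- summaries[code <= 7L, , drop = FALSE]
  }
  rownames(summaries) <- NULL
  summaries
}

#' ROC curve and Youden-optimal cut-point
#'
#' The decision rule predicts the positive (sedentary) class when the metric
#' value is *below* the threshold. Candidate thresholds are the midpoints
#' between consecutive distinct sorted values, plus the two infinite
#' sentinels; sensitivity is `P(value < t | positive)` and specificity
#' `P(value >= t | negative)`. The returned threshold maximises the Youden
#' index `J = sensitivity + specificity - 1`, with ties broken toward the
#' larger threshold; the AUC is computed by the trapezoidal rule over the
#' full ROC curve (equivalent to the Mann-Whitney pairwise statistic).
#'
#' @param values numeric metric values (e.g. per-participant activity
#'   means, mg).
#' @param labels logical (or 0/1) vector; `TRUE` marks the sedentary
#'   positives. Both classes must be present.
#' @return object of class `cutpoint_result`: `threshold_mg`, `auc`,
#'   `sensitivity`, `specificity`, `youden`, and the data.frame
#'   `roc_points` (`threshold`, `fpr`, `tpr`).
#' @export
roc_youden <- function(values, labels) {
  labels <- as.logical(labels)
  stopifnot(length(values) == length(labels), !anyNA(values), !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("both classes must be present")
  }
  sv <- sort(unique(values))
  cand <- c(-Inf, if (length(sv) > 1L) (head(sv, -1L) + tail(sv, -1L)) / 2,
            Inf)
  pos <- values[labels]; neg <- values[!labels]
  tpr <- vapply(cand, function(t) mean(pos < t), 0)
  fpr <- vapply(cand, function(t) mean(neg < t), 0)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tail(tpr, -1L)) / 2)
  j <- tpr - fpr
  best <- max(which(j >= max(j) - 1e-12))
  structure(list(threshold_mg = cand[best], auc = auc,
                 sensitivity = tpr[best], specificity = 1 - fpr[best],
                 youden = j[best],
                 n_pos = length(pos), n_neg = length(neg),
                 roc_points = data.frame(threshold = cand, fpr = fpr,
                                         tpr = tpr)),
            class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(paste0("<cutpoint_result> threshold = %.1f mg ",
                     "(AUC %.3f, %s; sens %.2f, spec %.2f; %d pos / %d neg)\n"),
              x$threshold_mg, x$auc, classify_auc(x$auc),
              x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

#' Qualitative AUC band
#'
#' @param auc numeric in `[0, 1]`.
#' @return `"poor"` (< 0.70), `"fair"` (0.70-0.79), `"good"` (0.80-0.89) or
#'   `"excellent"` (>= 0.90).
#' @export
classify_auc <- function(auc) {
  stopifnot(is.numeric(auc))
  if (any(auc < 0 | auc > 1)) stop("auc must be in [0, 1]")
  cut(auc, breaks = c(-Inf, 0.7, 0.8, 0.9, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent")) |> as.character()
}

#' Derive laboratory cut-points from a synthetic cohort
#'
#' Convenience driver: simulates `n_participants` laboratory sessions,
#' computes per-activity trimmed means, and runs the ROC/Youden analysis for
#' both metrics under the requested labelling scheme. The unit of analysis
#' is the per-participant per-activity mean.
#'
#' @param n_participants cohort size (default 35).
#' @param seed master seed; each participant uses a derived sub-seed.
#' @param scheme labelling scheme, see [label_activities()].
#' @param amp amplitude model, see [default_amplitude_model()].
#' @param sensor a [sensor_spec()].
#' @param trim_s per-bout trim, seconds.
#' @return list with elements `enmo` and `mad` ([roc_youden()] results) and
#'   `summaries` (the pooled labelled activity means).
#' @export
derive_lab_cutpoints <- function(n_participants = 35, seed = 1L,
                                 scheme = "sed_vs_nonsed",
                                 amp = default_amplitude_model(),
                                 sensor = sensor_spec(), trim_s = 30) {
  script <- lab_protocol_script()
  rows <- list()
  for (p in seq_len(n_participants)) {
    lab <- generate_lab_recording(script, amp, sensor,
                                  seed = (seed * 10007L + p) %% 2147483647L)
    es <- epoch_series(lab$recording)
    rows[[p]] <- activity_means(es, lab$script, trim_s, participant_id = p)
  }
  summaries <- label_activities(do.call(rbind, rows), scheme)
  list(enmo = roc_youden(summaries$mean_enmo_mg, summaries$sedentary),
       mad = roc_youden(summaries$mean_mad_mg, summaries$sedentary),
       summaries = summaries)
}
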