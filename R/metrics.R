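.epoch_matrix <- function(values, spe) {
  ne <- length(values) %/% spe
  if (ne < 1L) stop("recording shorter than one epoch")
  matrix(values[seq_len(ne * spe)], nrow = spe)
}

#' ENMO per epoch
#'
#' Euclidean Norm Minus One: per sample, the vector magnitude minus 1 g with
#' negative values truncated to zero; epoch values are the mean of the
#' truncated per-sample values over each half-open epoch `[t, t + epoch_s)`,
#' expressed in mg. A trailing partial epoch is dropped.
#'
#' @param rec a calibrated [raw_recording()].
#' @param epoch_s epoch length in seconds (must give an integer number of
#'   samples per epoch).
#' @return numeric vector of epoch ENMO values, mg.
#' @export
enmo_epochs <- function(rec, epoch_s = 5) {
  spe <- epoch_s * rec$sample_rate_hz
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_s times sample rate must be an integer")
  }
  e <- pmax(sample_magnitude(rec) - 1, 0)
  1000 * .colMeans(.epoch_matrix(e, as.integer(round(spe))),
                   as.integer(round(spe)),
                   length(e) %/% as.integer(round(spe)))
}

#' MAD per epoch
#'
#' Mean Amplitude Deviation: within each epoch, gravity is estimated as the
#' epoch's mean vector magnitude, and MAD is the mean absolute deviation of
#' the per-sample magnitudes around that mean, in mg. A trailing partial
#' epoch is dropped.
#'
#' @inheritParams enmo_epochs
#' @return numeric vector of epoch MAD values, mg.
#' @export
mad_epochs <- function(rec, epoch_s = 5) {
  spe <- epoch_s * rec$sample_rate_hz
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_s times sample rate must be an integer")
  }
  spe <- as.integer(round(spe))
  m <- .epoch_matrix(sample_magnitude(rec), spe)
  ne <- ncol(m)
  mu <- .colMeans(m, spe, ne)
  dev <- abs(m - rep(mu, each = spe))
  1000 * .colMeans(dev, spe, ne)
}

#' Epoch series of ENMO and MAD with wear flags
#'
#' @param rec a calibrated [raw_recording()].
#' @param epoch_s epoch length, seconds (default 5).
#' @param nonwear optional logical vector of per-epoch non-wear flags (as
#'   from [detect_nonwear()]); worn epochs are flagged `"worn"`.
#' @return data.frame of class `epoch_series` with columns `time` (epoch
#'   start), `enmo_mg`, `mad_mg`, `wear` (`worn`/`nonwear`/`imputed`);
#'   attributes `epoch_s`.
#' @export
epoch_series <- function(rec, epoch_s = 5, nonwear = NULL) {
  enmo <- enmo_epochs(rec, epoch_s)
  mad <- mad_epochs(rec, epoch_s)
  ne <- length(enmo)
  wear <- rep("worn", ne)
  if (!is.null(nonwear)) {
    stopifnot(length(nonwear) == ne)
    wear[nonwear] <- "nonwear"
  }
  out <- data.frame(time = rec$start_time + (seq_len(ne) - 1L) * epoch_s,
                    enmo_mg = enmo, mad_mg = mad, wear = wear)
  attr(out, "epoch_s") <- epoch_s
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' Detect non-wear periods
#'
#' Classifies the recording in 15-min blocks: a block is non-wear when, in
#' its surrounding 60-min window, at least `min_axes` of the three axes are
#' simultaneously quiet (standard deviation below `sd_threshold_mg` and
#' value range below `range_threshold_mg`). Block decisions are broadcast to
#' the 5-s epoch grid. A recording shorter than one window is returned as
#' fully worn.
#'
#' @param rec a calibrated [raw_recording()].
#' @param epoch_s epoch length for the output flags.
#' @param block_min decision block length, minutes.
#' @param window_min surrounding evaluation window, minutes.
#' @param sd_threshold_mg,range_threshold_mg per-axis stillness criteria, mg.
#' @param min_axes number of quiet axes required.
#' @return logical vector, one element per epoch (`TRUE` = non-wear).
#' @export
detect_nonwear <- function(rec, epoch_s = 5, block_min = 15, window_min = 60,
                           sd_threshold_mg = 13, range_threshold_mg = 50,
                           min_axes = 2) {
  rate <- rec$sample_rate_hz
  n <- nrow(rec$data)
  ne <- n %/% as.integer(round(epoch_s * rate))
  flags <- rep(FALSE, ne)
  spw <- as.integer(round(window_min * 60 * rate))
  if (n < spw) return(flags)
  spb <- as.integer(round(block_min * 60 * rate))
  nb <- ceiling(n / spb)
  half <- spw %/% 2L
  sd_thr <- sd_threshold_mg / 1000
  rg_thr <- range_threshold_mg / 1000
  ep_per_block <- as.integer(round(block_min * 60 / epoch_s))
  for (b in seq_len(nb)) {
    centre <- (b - 1L) * spb + spb %/% 2L
    lo <- max(1L, centre - half); hi <- min(n, centre + half)
    if (hi - lo + 1L < spw) {  # clamp window inside the recording
      if (lo == 1L) hi <- min(n, spw) else lo <- max(1L, n - spw + 1L)
    }
    quiet <- 0L
    for (j in 1:3) {
      v <- rec$data[lo:hi, j]
      if (sd(v) < sd_thr && diff(range(v)) < rg_thr) quiet <- quiet + 1L
    }
    if (quiet >= min_axes) {
      e_lo <- (b - 1L) * ep_per_block + 1L
      e_hi <- min(ne, b * ep_per_block)
      if (e_lo <= e_hi) flags[e_lo:e_hi] <- TRUE
    }
  }
  flags
}

#' Impute non-wear epochs from matching clock times on other days
#'
#' Each non-wear epoch is replaced by the mean of worn-epoch metric values at
#' the same clock offset on the other days of the recording, and flagged
#' `imputed`. Non-wear epochs with no worn donor at their clock slot on any
#' other day are left at zero and keep the `nonwear` flag (unimputable).
#' Worn epochs are preserved bit-exactly.
#'
#' @param series an [epoch_series()].
#' @return the imputed `epoch_series`.
#' @export
impute_nonwear <- function(series) {
  nw <- series$wear == "nonwear"
  if (!any(nw)) return(series)
  epoch_s <- attr(series, "epoch_s") %||% 5
  tnum <- as.numeric(series$time)
  slot <- as.integer((tnum %% 86400) %/% epoch_s)
  worn <- series$wear == "worn"
  for (m in c("enmo_mg", "mad_mg")) {
    sums <- tapply(series[[m]][worn], slot[worn], sum)
    cnts <- tapply(rep(1, sum(worn)), slot[worn], sum)
    key <- as.character(slot[nw])
    donor <- unname(sums[key] / cnts[key])
    series[[m]][nw] <- ifelse(is.na(donor), 0, donor)
  }
  key <- as.character(slot[nw])
  has_donor <- key %in% names(tapply(rep(1, sum(worn)), slot[worn], sum))
  series$wear[which(nw)[has_donor]] <- "imputed"
  series
}
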