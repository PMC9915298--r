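.check_pairs <- function(pairs, min_n = 2L) {
  stopifnot(all(c("criterion", "comparison") %in% names(pairs)))
  if (anyNA(pairs$criterion) || anyNA(pairs$comparison)) {
    stop("missing values in pairs")
  }
  if (nrow(pairs) < min_n) stop("need at least ", min_n, " pairs")
  pairs
}

#' Mean (absolute) percent error
#'
#' Per-record percent error is `e_i = 100 * (criterion_i - comparison_i) /
#' comparison_i`; MPE is its mean (signed agreement at the group level) and
#' MAPE the mean of `|e_i|` (individual-level error). Records with a zero
#' comparison value are excluded with a warning. Note the sign convention:
#' a comparison method that overestimates the criterion yields a negative
#' MPE.
#'
#' @param pairs data.frame with columns `criterion` and `comparison`
#'   (minutes, one row per analysis unit).
#' @return list with `mpe_pct`, `mpe_sd`, `mape_pct`, `mape_sd`, `n`.
#' @export
mpe_mape <- function(pairs) {
  pairs <- .check_pairs(pairs)
  zero <- pairs$comparison == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero comparison value excluded")
    pairs <- pairs[!zero, , drop = FALSE]
  }
  e <- 100 * (pairs$criterion - pairs$comparison) / pairs$comparison
  list(mpe_pct = mean(e), mpe_sd = sd(e),
       mape_pct = mean(abs(e)), mape_sd = sd(abs(e)), n = length(e))
}

#' Bland-Altman bias and limits of agreement
#'
#' On the absolute scale the differences are `criterion - comparison`
#' (minutes); on the percent scale each difference is expressed relative to
#' the pair mean, `100 * (criterion - comparison) / ((criterion +
#' comparison) / 2)`. The bias is the mean difference and the 95% limits of
#' agreement are `bias +/- 1.96 * sd(differences)`.
#'
#' @param pairs data.frame with columns `criterion`, `comparison` (>= 3
#'   rows; the SD of differences is unstable below that).
#' @param scale `"absolute"` or `"percent"`.
#' @return list with `bias`, `loa_lo`, `loa_hi`, `sd_diff`, `n`.
#' @export
bland_altman <- function(pairs, scale = c("absolute", "percent")) {
  scale <- match.arg(scale)
  pairs <- .check_pairs(pairs, min_n = 3L)
  d <- if (scale == "absolute") {
    pairs$criterion - pairs$comparison
  } else {
    100 * (pairs$criterion - pairs$comparison) /
      ((pairs$criterion + pairs$comparison) / 2)
  }
  bias <- mean(d); s <- sd(d)
  list(bias = bias, loa_lo = bias - 1.96 * s, loa_hi = bias + 1.96 * s,
       sd_diff = s, n = length(d))
}

#' Percent-scale bias from group means
#'
#' Expresses an absolute Bland-Altman bias relative to the mean of the two
#' methods' group means: `100 * bias / ((criterion_mean + comparison_mean)
#' / 2)`. Useful to convert a reported bias in minutes into the relative
#' bias conventionally quoted alongside it.
#'
#' @param criterion_mean,comparison_mean group means (minutes/day).
#' @param bias absolute bias (criterion minus comparison), minutes/day.
#' @return relative bias, percent.
#' @export
percent_scale_bias <- function(criterion_mean, comparison_mean, bias) {
  100 * bias / ((criterion_mean + comparison_mean) / 2)
}

#' Minimal equivalence zone
#'
#' Finds the smallest symmetric zone around the criterion mean — scanned in
#' 1-percentage-point steps — such that the two-sided 95% confidence
#' interval of the comparison mean lies entirely within
#' `[criterion_mean * (1 - delta), criterion_mean * (1 + delta)]`. The zone
#' is also expressed as a multiple of the criterion SD (to 0.1 SD), which
#' makes zones comparable across outcomes with different spreads.
#'
#' @param pairs data.frame with columns `criterion`, `comparison` (>= 2
#'   rows).
#' @param level confidence level of the comparison-mean CI (default 0.95).
#' @param max_pct largest zone scanned, percent.
#' @return list with `zone_pct`, `zone_sd_multiple`, `ci_lo`, `ci_hi`,
#'   `criterion_mean`.
#' @export
equivalence_zone <- function(pairs, level = 0.95, max_pct = 100) {
  pairs <- .check_pairs(pairs, min_n = 2L)
  n <- nrow(pairs)
  mc <- mean(pairs$criterion)
  mx <- mean(pairs$comparison)
  half <- qt(1 - (1 - level) / 2, n - 1L) * sd(pairs$comparison) / sqrt(n)
  ci <- c(mx - half, mx + half)
  for (z in seq_len(max_pct)) {
    d <- z / 100
    if (ci[1L] >= mc * (1 - d) && ci[2L] <= mc * (1 + d)) {
      return(list(zone_pct = z,
                  zone_sd_multiple = round(d * mc / sd(pairs$criterion), 1),
                  ci_lo = ci[1L], ci_hi = ci[2L], criterion_mean = mc))
    }
  }
  stop("no equivalence zone up to ", max_pct, "% contains the CI")
}

#' Full agreement report
#'
#' Bundles [mpe_mape()], absolute and percent [bland_altman()] and the
#' minimal [equivalence_zone()] for one criterion-comparison pairing.
#'
#' @param pairs data.frame with columns `criterion`, `comparison`.
#' @return object of class `agreement_report`.
#' @export
agreement_report <- function(pairs) {
  structure(list(pe = mpe_mape(pairs),
                 ba_abs = bland_altman(pairs, "absolute"),
                 ba_pct = bland_altman(pairs, "percent"),
                 equivalence = equivalence_zone(pairs),
                 criterion_mean = mean(pairs$criterion),
                 comparison_mean = mean(pairs$comparison),
                 n = nrow(pairs)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> n = %d units\n", x$n))
  cat(sprintf("  criterion %.1f vs comparison %.1f min/d\n",
              x$criterion_mean, x$comparison_mean))
  cat(sprintf("  MPE %.1f +/- %.1f %%; MAPE %.1f +/- %.1f %%\n",
              x$pe$mpe_pct, x$pe$mpe_sd, x$pe$mape_pct, x$pe$mape_sd))
  cat(sprintf("  bias %.1f min [LoA %.1f, %.1f]; %.1f%% [%.1f, %.1f]\n",
              x$ba_abs$bias, x$ba_abs$loa_lo, x$ba_abs$loa_hi,
              x$ba_pct$bias, x$ba_pct$loa_lo, x$ba_pct$loa_hi))
  cat(sprintf("  equivalence zone %d%% (%.1f SD)\n",
              x$equivalence$zone_pct, x$equivalence$zone_sd_multiple))
  invisible(x)
}
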