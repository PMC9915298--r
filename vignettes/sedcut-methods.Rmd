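---
title: "Deriving and evaluating sedentary-time cut-points from thigh-worn raw accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and evaluating sedentary-time cut-points from thigh-worn raw accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedcut)
```

## The problem

Thigh-worn tri-axial accelerometers are the reference instrument for
measuring sedentary behaviour (SB): waking time spent sitting, reclining or
lying. Posture-detection software reports SB directly, but many studies
instead process the *raw* acceleration signal into open, device-agnostic
metrics — ENMO and MAD, both in milli-gravitational units (mg) — and
classify 5-s epochs as sedentary when the metric falls below a cut-point.
`sedcut` implements the full workflow needed to derive such cut-points in a
scripted laboratory protocol and to evaluate them against a criterion
posture-event measure during free living:

1. **Signal simulation** with posture ground truth (`generate_lab_recording()`,
   `generate_freeliving_recording()`), since raw recordings with criterion
   events are rarely shareable.
2. **Auto-calibration** of the raw signal to local gravity
   (`find_stationary_windows()`, `fit_calibration()`), with the
   post-calibration error as the file-inclusion criterion.
3. **Epoch metrics**: ENMO and MAD over 5-s epochs, non-wear detection and
   same-clock-time imputation (`enmo_epochs()`, `mad_epochs()`,
   `detect_nonwear()`, `impute_nonwear()`).
4. **Cut-point derivation** from per-participant activity means by
   ROC/Youden analysis (`activity_means()`, `roc_youden()`).
5. **Free-living evaluation**: daily criterion vs cut-point sedentary
   minutes over identical waking windows (`daily_summaries()`), summarised
   by MPE/MAPE, Bland-Altman limits of agreement and minimal equivalence
   zones (`agreement_report()`).

## Metric definitions and numerical conventions

For a calibrated sample vector $(x, y, z)$ in g with magnitude
$r = \sqrt{x^2+y^2+z^2}$:

* **ENMO** is $\max(r - 1, 0)$ applied per sample *before* epoch averaging,
  then averaged over the half-open epoch $[t, t+5\,\mathrm{s})$ and scaled
  to mg. Per-sample truncation is the metric's published definition; it
  matters whenever $r$ oscillates around 1 g (a magnitude alternating
  0.9/1.1 g gives 50 mg, not 0).
* **MAD** estimates gravity as the epoch's own mean magnitude $\bar r$ and
  averages $|r_i - \bar r|$ over the epoch (the same alternating signal
  gives 100 mg). We compute MAD on the 5-s epoch grid itself rather than a
  separate moving window, since a single 5-s grid is what the epoch outputs
  are defined on.
* Epochs are half-open; a trailing partial epoch is dropped. Both metrics
  depend on the signal only through $r$, so they are rotation-invariant —
  property-tested with random rotation matrices.

**Calibration.** Stationary windows are 10-s non-overlapping windows with
per-axis SD below 13 mg (windows containing range-clipped samples are
discarded). The fit is an iterated per-axis linear regression of each
calibrated point against its projection on the unit sphere, stopping when
the mean absolute residual changes by less than `1e-9` (at most 100
iterations). The fit is refused — returning an identity model flagged
non-converged, as with short laboratory files where back-up coefficients
from another wear of the same device are the practical fallback — unless at
least 10 stationary points cover both signs beyond 300 mg on every axis.
These stillness/coverage parameters are the processing defaults published
for this class of pipeline; the 0.02 g inclusion criterion is only
meaningful relative to them.

**Non-wear.** A 15-min block is non-wear when, in its surrounding 60-min
window, at least two axes are simultaneously quiet (SD < 13 mg and range
< 50 mg). Non-wear epochs are imputed by the mean of worn epochs at the
same clock offset on the other days; epochs with no donor stay flagged and
invalidate their day. Imputed epochs contribute to classification (flagged
in the output), since wear-validity and classification use the same series.

**ROC/Youden.** The unit of analysis is the per-participant per-activity
trimmed mean (the first and last 30 s of each bout are excluded; a 5-min
activity contributes 48 five-second epochs). Sedentary is the positive
class, predicted when the value is *below* the threshold. Candidate
thresholds are midpoints between consecutive distinct values plus the
infinite sentinels; ties on the Youden index break toward the larger
threshold (an interior criterion). The trapezoidal AUC equals the
Mann-Whitney pairwise statistic, which the tests verify exhaustively on
small instances and against an independent ROC implementation.

**Free-living accounting.** Days are calendar-aligned
(midnight-to-midnight); a day is valid only with complete 24-h epoch
coverage and no unimputable epochs. Waking time is the day minus every
in-bed interval portion falling within it, taken from a sleep log built
from the ground-truth in-bed events — applied identically to the criterion
and estimate paths so both are compared over the same timeframe. (Crediting
a midnight-crossing bed interval only to the evening it starts would leave
the previous night's early-morning hours inside the next day's waking
window; clipping intervals to days avoids that while preserving identical
treatment of both paths.) Epochs straddling a bed boundary count as waking
iff their start lies outside the bed interval; classification uses a strict
`value < cutpoint` comparison.

**Agreement statistics.** Percent errors are
$100\,(\mathrm{criterion}-\mathrm{comparison})/\mathrm{comparison}$; MPE is
their mean and MAPE the mean of their absolute values (so MAPE $\ge$ |MPE|
always, but an overestimating comparison yields a *negative* MPE — means
alone cannot recover every published sign pattern because per-record skew
can flip the group-level sign, which is why per-record values are
available). Bland-Altman limits are bias $\pm 1.96$ SD of the differences,
on the absolute scale or relative to pair means. The equivalence zone scans
1-percentage-point steps for the smallest symmetric interval around the
criterion mean containing the two-sided 95% CI of the comparison mean; we
use the literal 95% CI (not the TOST-conventional 90%) deliberately, and
express the zone also as a multiple of the criterion SD (to 0.1 SD), using
the SD of the criterion's participant-level means. The default unit of
analysis is the participant mean of daily values; day-level analysis is a
matter of passing day rows instead.

## What the synthetic data emulate — and what they do not

No public raw recordings with criterion posture events accompany this
problem, so the generator is a first-class module with ground truth rather
than a test fixture.

**Geometry.** The device's longitudinal axis is `z`. Upright bouts place
gravity within 15° of `+z`; seated/lying bouts within 20° of the transverse
plane with a fresh azimuth (at least 30° from the previous one) per bout.
Nightly in-bed intervals contain posture turns every 15–40 min with tilt up
to 40° from horizontal — bent-knee and rolled positions tilt the thigh far
more in bed than daytime sitting does, and those night-time orientations
are what give the stationary point cloud both signs of `z` beyond the
sphere-coverage bound. These
choices make the stationary point cloud cover the sphere the way week-long
wear does, which is what gives auto-calibration its leverage; they also
guarantee a posture transition inside any one-hour window, so stillness
never masquerades as non-wear (a deliberate simplification — real sleepers
can lie still longer, and real pipelines do occasionally flag quiet sleep
as non-wear).

**Movement.** Each bout's magnitude trace is
$1 + b + A\sin(2\pi f t + \phi)$ with $f$ in 0.5–3 Hz, plus a weaker (0.3 A)
transverse oscillation and white sensor noise. Per epoch, $A$ is solved
from the target MAD and $b$ from the target ENMO using noise-aware closed
forms ($\mathbb{E}|\mu+\varepsilon|$ and
$\mathbb{E}\max(\mu+\varepsilon,0)$ averaged over phase), so the *epoch
metrics* hit the requested distributions even near the noise floor. The
waveform itself is not a gait model: frequency content, harmonics and axis
coupling are not claims the package makes, and nothing downstream depends
on them beyond the epoch metrics.

**Amplitude targets.** Upright activities use published thigh medians and
quartiles for this protocol (e.g. self-paced walking MAD median 316.3 mg,
IQR 268.7–370.2; quiet standing MAD 4.5 mg with a heavy ENMO tail). The
pooled sedentary class (median 4.0, IQR 1.8–9.1 mg MAD) is decomposed into
six gently increasing per-activity medians (2.4–9.2 mg) with
between-participant log-SD 0.35, truncated at 2.5 SD. The pooled spread
this produces is somewhat narrower than the published pooled IQR; the
trade-off is intentional: with the full pooled spread assigned to every
activity independently, the largest of 210 sedentary means would routinely
overshoot the smallest ambulatory mean, and no threshold could separate
them — contradicting the protocol's design premise that lying/sitting and
ambulation are separable. ENMO targets are rank-coupled to MAD with their
own log-spread (a power transform of the shared multiplier), preserving
each metric's marginal quartiles.

**Free-living behaviour.** Defaults: 8.1 h in bed from ~23:00 (SD 20 min
start jitter, 25 min duration), participant waking sedentary fraction
0.575 (SD 0.089 between participants, 0.04 day-to-day) — so criterion
sedentary time averages ≈550 min/day with a ≈85 min/day participant SD —
sedentary bouts of median 15 min and upright bouts of median 8 min (both
capped at 40 min), upright time split 4% quiet standing / 72% standing
with light movement (MAD median 70 mg, ENMO ≈ 0.62 MAD) / 24% stepping.
Sedentary epochs get a heavy-tailed multiplier (log-SD 1.2, matching the
pooled quartiles) to emulate fidgeting. These choices reproduce the
*mechanism* behind the field observation that an ENMO cut-point
overestimates free-living sedentary time while a MAD cut-point tracks the
criterion closely: near the cut-points, light standing movement carries
proportionally less ENMO than MAD (as the walking and stairs rows show),
so more of it falls below the ENMO threshold; meanwhile sedentary fidget
epochs above the MAD threshold roughly offset the quiet standing epochs
below it. Passing the ordering tests therefore shows the pipeline
propagates these distributional differences correctly — it does not
validate the cut-points on real wearers, and the simulated world contains
no posture–movement dissociations beyond the ones built in (no cycling,
no standing desks with motion, no device micro-movement during non-wear).

**Problem sizes.** The evaluation cohort used by the tests is 38
participants × 6 days at 20 Hz (two participants record only a 30-h
mid-day-to-mid-day window and so have no complete calendar day); the
calibration targets use ten seeded 7-day recordings per noise level; the
laboratory cohort is 35 participants × 70 min. These sizes keep every
statistic at its intended unit of analysis (36 retained participants,
participant-level agreement) while each simulation remains a few seconds
of compute.

## A worked laboratory example

```{r lab, eval = FALSE}
res <- derive_lab_cutpoints(n_participants = 35, seed = 1)
res$mad
#> <cutpoint_result> threshold = 25.8 mg (AUC 0.905, excellent; sens 1.00, spec 0.83; 210 pos / 210 neg)
res$enmo
#> <cutpoint_result> threshold = 20.9 mg (AUC 0.902, excellent; sens 1.00, spec 0.86; 210 pos / 210 neg)
```

The derived MAD threshold always lies strictly between the largest
sedentary activity mean and the smallest ambulatory activity mean — the
quiet-standing negatives overlapping the sedentary class put a ceiling on
specificity (and on the AUC) but do not move the optimum out of the gap.
Isolating quiet standing as the sole negative class
(`scheme = "sed_vs_passive_standing"`) reproduces the qualitative result
that sedentary-vs-standing discrimination is poor (here AUC 0.41, i.e. at
or below chance) even though sensitivity at the optimum stays high (0.96).

## Known limitations

* The generator's defaults describe one young-adult cohort; population or
  protocol shifts (older adults, different wear sites) require new
  amplitude tables.
* Criterion events are ground truth by construction; disagreement between
  a real posture classifier and true posture is outside the simulated
  world, so free-living agreement here is an upper bound on what identical
  processing can achieve.
* The equivalence zone follows the literal stated procedure (CI of the
  comparison mean vs a zone around the criterion mean); a paired-difference
  TOST is a plausible alternative reading and would give slightly different
  zones.
* Percent-scale Bland-Altman limits are computed from per-pair relative
  differences and are not algebraically recoverable from the absolute
  limits and group means; both scales are reported separately.
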