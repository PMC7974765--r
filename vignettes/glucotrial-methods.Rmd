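---
title: "Methods: CGM cross-over analytics in glucotrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CGM cross-over analytics in glucotrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glucotrial)
```

# Scope and data model

`glucotrial` analyzes remote trials in which each subject wears a flash
continuous glucose monitor (CGM) and keeps a smartphone log. The sensor
estimates interstitial glucose every 15 minutes and holds the most recent
8 hours in memory; a scan downloads that buffer. Three consequences shape
the data model:

* a subject's record is a union of overlapping 8-hour blocks
  (`merge_scan_downloads()`), with genuinely unrecoverable stretches
  whenever consecutive scans are more than 8 hours apart — these are kept
  as explicit gap intervals, never imputed;
* scan timing is itself an outcome: it measures engagement
  (`scan_gap_stats()`);
* all timestamps are stored in UTC while day-based metrics (peaks/day,
  logs/day) are computed on local calendar days, because the behaviors
  being counted are circadian.

Glucose values outside (0, 500) mg/dL are rejected at parse as device
artefacts; the bounds are a convention of this package, chosen from the
reporting range of commercial sensors. Duplicate timestamps with equal
values collapse silently (overlapping buffers legitimately repeat data);
conflicting values are an integrity error, because they cannot both be the
sensor's record.

Window slicing is closed on both ends. This makes the meal-tolerance-test
arithmetic exact: a 2-hour window on the 15-minute grid contains 9
samples, so four tests contribute 36 points per subject.

# The primary endpoint

A fasted meal-tolerance test (MTT) is a standardized 45-g carbohydrate
challenge after a ≥ 6-hour fast. For the 2-hour window after intake at
$t_0$, with baseline $b = g(t_0)$, the incremental AUC integrates
$\max\{g(t)-b, 0\}$ trapezoidally on the 15-minute grid. The
positive-increment convention is the default because the clinical
literature on incremental AUC for glycemic responses uses it; the signed
`net` convention is available and recorded in every result. Units are
(mg/dL)·min, a time-integral of a concentration.

When the annotated intake time falls between sensor samples, the baseline
is linearly interpolated between the bracketing samples, the grid is
anchored at $t_0$, and the result is flagged `interpolated`. A grid point
is considered covered when a sample lies within half a grid step; a window
with under 75% of its grid points covered is rejected as insufficient
data rather than silently extrapolated.

Per subject, the four labelled MTTs give within-arm changes
$\Delta\mathrm{AUC} = \mathrm{AUC}_{end} - \mathrm{AUC}_{begin}$ and the
cross-over contrast $\Delta\Delta\mathrm{AUC} =
\Delta\mathrm{AUC}_{product} - \Delta\mathrm{AUC}_{placebo}$; the identity
is enforced exactly. No period- or carryover-effect model is fitted: the
analysis is the paired contrast, which is what the small-sample design
supports.

## The exact signed-rank test

The cohort test is one-sided Wilcoxon signed-rank on the per-subject
contrasts ($H_0$: contrasts $\ge 0$). At pilot sample sizes the normal
approximation is unreliable and lookup tables break under ties, so for
$n \le 20$ the package computes the exact null distribution of $W^+$ by
enumerating all $2^n$ sign assignments of the (mid-)ranked absolute
values, implemented as an integer convolution over doubled ranks — exact
even with ties. The reported one-sided p-value is
$P(W^+ \le w_{obs})$ for alternative `less`.

Small-sample signed-rank p-values are convention-sensitive: software
differs in zero handling, tie treatment, and whether the discrete tail is
taken at or strictly beyond the observed statistic, and such differences
move a six-subject p-value by whole sixty-fourths. This package fixes and
documents one convention (zeros dropped; mid-ranks; closed tail by full
enumeration) and does not attempt to match any other tool's rounding.
Above $n = 20$ a normal approximation with tie-corrected variance and a
0.5 continuity correction takes over; the `method` field always records
which path produced the p-value.

## Power by simulation

`power_by_simulation()` draws each replicate's $n$ contrasts from a normal
law with a stated mean and SD, applies the exact test at level $\alpha$,
and reports the rejection fraction with its Monte-Carlo standard error.
The normal effect model is a deliberate simplification: the test itself is
rank-based, so power depends on the effect distribution mainly through
$P(\text{contrast} < 0)$, and a location-scale family is the natural
planning model. Default runs use 20,000 replicates, giving a Monte-Carlo
SE below 0.4 percentage points.

## Baseline stratification

Subjects are split on baseline MTT AUC by a configurable cutoff (default
1000 (mg/dL)·min). A cutoff was chosen over clustering deliberately:
on small cohorts, largest-gap and 2-means rules are dominated by the most
extreme subject and fail to separate moderate from low baseline glycemic
control, whereas a cutoff is transparent, pre-specifiable, and echoed back
in the result.

# Peak detection

Scoring uses the simplest spike function of the Palshikar family:
$s_i = \tfrac12\big(\max_{j\le k}(x_i - x_{i-j}) + \max_{j\le k}(x_i -
x_{i+j})\big)$ with $k = 4$ samples (one hour each side), after a
3-sample moving average. The threshold is adaptive — mean plus $h$ SD of
the positive scores ($h = 1$) — so it transfers across subjects with
different variability. Candidates closer than 60 minutes merge; the apex
is the cluster's glucose maximum; the extent walks outward until the
curve returns within 10% of the prominence above the local baseline (the
minimum smoothed glucose within ±2 hours), a renewed rise begins, or a
sampling gap intervenes. Candidates with prominence under 20 mg/dL are
dropped: at a sensor noise SD of ~5 mg/dL this separates meal responses
from noise fluctuations. Scores, baselines and prominences are built from
differences only, so detection is invariant to a constant shift of the
trace. Peaks are returned time-ordered and pairwise disjoint, with
overlapping extents cut at the inter-apex glucose minimum.

The extent criterion and the threshold form are this package's choices;
spike-function peak detection is published as a scoring rule, not a full
segmentation algorithm, and the shaded-extent displays it is usually
paired with are not formally defined anywhere we could adopt.

# Compliance analytics

* `scan_gap_stats()` reports inter-scan intervals, the count exceeding
  the 8-hour buffer, the exact unsampled duration
  $\sum \max(0, \text{interval} - 8\,h)$, weekly medians and the sign of
  the first-to-last-week change (scan fatigue shows as +1).
* `fasting_precheck()` checks the 6 hours before an MTT: verdicts are
  `insufficient_data` (< 75% of expected samples), `flagged`
  (max-minus-min excursion above 25 mg/dL, or a detected peak overlapping
  the window), else `pass`. The 25 mg/dL default is this package's
  convention for "flat": roughly five noise SDs, small enough to catch a
  40 mg/dL overnight excursion, large enough to ignore circadian drift.
* `annotation_rate_stats()` counts app logs per local calendar day
  (empty days count as zero) and reports the variance-to-mean ratio and
  weekly trend.

# Glycemic metrics

Consensus thresholds: time in range is the sample-weighted fraction in
[70, 180] mg/dL, boundaries inclusive; hypoglycemic episodes are maximal
runs of ≥ 2 consecutive samples strictly below 70 mg/dL (≥ 30 minutes of
nominal time), never bridged across a sampling gap — "consecutive"
requires contiguity on the grid; the 2-hour postprandial check reads the
nearest sample within 15 minutes of intake + 120 min (else interpolates
between the bracketing pair) and flags values ≥ 140 mg/dL. "Below 70" is
strict while the range boundaries are inclusive, mirroring how the
thresholds are phrased in clinical guidance; both conventions are fixed
here and tested.

# The synthetic-data generator

The generator is the package's test bed and defines the conditions under
which the pipeline's properties are demonstrated. A trace is

$$ g(t) = b + A\cos\!\Big(\tfrac{2\pi (t_{local} - 8\,h)}{24\,h}\Big)
   + \sum_{meals} M(t - t_{meal}) + \varepsilon_t $$

with subject baseline $b \sim N(95, 10^2)$ mg/dL, circadian amplitude
$A = 8$ mg/dL peaking at 08:00 local (a dawn-phase rise), and i.i.d.
Gaussian sensor noise with SD 5 mg/dL (an optional AR(1) knob exists;
interstitial sensors smooth, but the correlation is unspecified, so the
default is independence). Values below 40 mg/dL are clipped there and
counted — low enough to keep hypoglycemia testable, high enough to stay
physiological.

The meal impulse $M$ is a gamma-density-shaped curve parameterized by
what a trial scientist actually specifies: the apex
(carbs × 1.2 mg/dL per gram), the time to peak (45 min) and the return
time (120 min), with the gamma exponent solved in closed form so the
impulse decays to 5% of its apex at the return time. A 45-g standardized
meal therefore produces a ~54 mg/dL excursion peaking 45 minutes after
intake — the scale of a standardized nutritional drink in a non-diabetic
cohort. These magnitudes are conventions of the generator, not estimates
of any real cohort.

Treatment acts as a multiplier on the incremental response of the
product-period-end MTT meal (`product_effect`, default 0.7), so the
generator's contrast structure is linear by construction and parameter
recovery is checkable. Scan behavior draws log-normal inter-scan
intervals around a median (5 h) that drifts multiplicatively per week
(1.1× — scan fatigue), with a probability of buffer-overshooting
intervals; an activation scan at wear start and a device-return scan at
the end bracket the record, so data loss is pure buffer arithmetic.
`simulate_study()` assembles full cohorts: 14-day periods in alternating
arm order, 4-day washouts, three daily meals with breakfast skipped on
MTT mornings so the 6-hour fasting window stays quiet, and an app log
with meal photos (logged with probability 0.8), exercise, and
fingerstick entries.

What the generator does *not* emulate: insulin–glucose dynamics, sensor
drift and recalibration, meal-composition effects (fat-delayed
absorption), exercise-induced dips, or between-day habit correlation.
Passing tests demonstrate the pipeline's arithmetic, conventions and
statistical behavior under the stated stochastic structure — not accuracy
on any particular real cohort.

# Numerical choices and degenerate inputs

* Trapezoid integration on the closed 9-point grid; the test suite checks
  it against an independent midpoint-refinement oracle to 1e-9 relative.
* Exact-test tails are closed ($\le$, $\ge$); two-sided doubles the
  smaller tail, capped at 1.
* All-zero contrast vectors are a degenerate-input error, not p = 1.
* Stratification requires the cutoff strictly inside the data range;
  constant inputs are an argument error.
* Empty traces error in metrics; empty event logs return all-zero rates.
* Generators mutate the RNG stream only when given an explicit seed.

# Problem sizes used by the test suite

Chosen to exercise every property at meaningful resolution: 20,000
replicates for headline power runs (MC SE < 0.4 pp), 1,000–2,000 for
power properties inside the suite; 50 seeded synthetic days for
peak-recovery sensitivity/false-positive rates; an n = 200 simulated
cohort for pipeline-level parameter recovery; full enumeration up to
$n = 20$ (about $10^6$ sign assignments) when validating the normal
approximation.

# Known limitations

The pipeline deliberately stops short of mixed-effects cross-over
modelling (period and carryover effects are not estimated), of any
fingerstick-vs-sensor agreement analysis, and of reproducing
cohort-specific descriptive statistics such as total in-peak hours, which
depend on real traces and unpublished detector settings. The peak
detector's parameter defaults are tuned for 15-minute flash data; denser
CGM streams would need a larger $k$ and a narrower smoothing window.
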