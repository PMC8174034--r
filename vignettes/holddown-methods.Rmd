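---
title: "Methods: event-locked single-unit analysis of a hold-down task"
author: "holddown package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-locked single-unit analysis of a hold-down task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holddown)
```

## The task and the data model

In the self-paced hold-down (action differentiation) task, a mouse must keep
a lever depressed longer than a session criterion (800 ms early in training,
1600 ms late) to earn a food reward, which is delivered at the moment of
lever *release* — and only when the hold strictly exceeded the criterion.
Sessions have no trial structure: the animal initiates, holds, and releases
at will, and the session terminates after 60 rewards or 90 minutes,
whichever comes first. Behavioral events are timestamped on a 10-ms grid;
spike times of sorted orbitofrontal cortex (OFC) units are continuous.

`BehavioralSession` objects enforce this structure as S4 validity rules:
strictly increasing, non-overlapping presses; every reward equal to the
offset of exactly one super-criterion press; all behavioral times
nonnegative 10-ms multiples. Presses are half-open intervals
`[onset, offset)`, so a spike exactly at the offset belongs to the
post-press epoch. "Exceeded" is implemented strictly (`duration >
criterion`): a press exactly at criterion is a failure. Reward delivery is
identified with the rewarded press offset (zero modeled latency); any
hardware latency is absorbed into the outcome epoch.

## PETHs, baseline statistics and modulation detection

Spike counts are binned in 20-ms half-open bins over −10,000 to +10,000 ms
around each event and averaged over events, giving trial-averaged rates in
Hz. Because the task is self-paced, windows of nearby events may overlap
and a spike may legitimately count toward several events; no proximity
exclusion is applied. The averaged PETH is smoothed with a 3-bin
Gaussian-weighted moving average (taps `exp(-1/(2*sigma^2))`, 1, with
`sigma = 0.4` bins, normalized; truncated and renormalized at the edges so
constants are preserved). `sigma = 0.4` is the common windowed-Gaussian
convention for a 3-tap window and is configurable.

Baseline statistics come from the 400 smoothed bins between −10,000 and
−2,000 ms before press onset: mean, sample SD, and a 95% interval. Two
readings of "95% confidence interval above/below baseline activity" are
supported: the default treats the baseline *distribution* literally and
uses its empirical 2.5th/97.5th percentiles; `method = "parametric"` uses
mean ± 1.96 SD. The same press-onset baseline serves all three alignments
(onset, offset, reward), since a single baseline period is defined per
unit.

A unit is called **up-modulated** at an event if at least four consecutive
bins (80 ms) within −2,000 to +3,000 ms exceed the upper bound, and
**down-modulated** if four consecutive bins fall below the lower bound.
The source description requires consecutiveness explicitly only for the
down rule; we implement both symmetrically as consecutive runs, which is
the stricter and more defensible reading. When both patterns occur, the
earlier qualifying run determines the headline direction (ties go to up)
and both run onsets are retained. Modulation onset is the left edge of the
first bin of the first qualifying run. Degenerate zero-SD baselines simply
produce a degenerate percentile interval; any sustained deviation then
qualifies.

Z-scored PETHs use the baseline mean and SD per bin. With a zero-SD
baseline, bins at the mean get z = 0 and others are flagged undefined; such
units are excluded from group averages with a warning. Epoch summaries
average z over four consecutive 250-ms bins (pre-onset −1000..0; post-offset
and post-reward 0..+1000). Since 250/20 = 12.5, each 20-ms bin is assigned
to the 250-ms bin containing its left edge, giving the 13/12/13/12
partition.

## Within-press dynamics

Within-session duration quartiles are a **rank split**: presses sorted by
duration (ties by press order) are divided into four contiguous rank blocks
as equal as possible, remainder to the earliest quartiles. This guarantees
counts balanced within one press and is unambiguous under ties; boundaries
are reported as the maximum duration in Q1–Q3. (Interpolated percentile
cut points are the alternative reading; the rank split was chosen for its
balance guarantee.)

Each press is segmented into four equal duration quarters. Spike
proportions per segment are counts divided by the press's total in-press
count; zero-spike presses are undefined (0/0) and excluded from proportion
averages, while remaining in the spike-presence denominator. For
quartile-resolved firing profiles, segment *rates* (count ÷ quarter
length) are z-scored against a baseline "proportionate" to the quartile: a
window of length equal to the quartile's mean press duration immediately
before each onset, binned at 20 ms and pooled across that quartile's
presses (pooling is our choice, for SD stability at small per-press
baseline lengths). Rates rather than raw counts make quartiles of
different durations comparable before z-scoring.

## Pseudo-population decoding

For sessions with at least 10 successful presses, per-unit peri-event
rasters (1-ms bins, −2,000 to +10,000 ms) are labeled by press outcome.
Pseudo-trials pair independently drawn events across units recorded in
different sessions — the standard pseudo-population construction; within-
session noise correlations are consequently not preserved, a documented
limitation. Per resampling run, each unit contributes `nPerClass` freshly
drawn success and failure events without replacement (default: the minimum
per-class count over eligible units).

Features are spike counts in 200-ms windows stepped every 100 ms,
z-scored per unit by *training-fold* statistics (test folds never leak
into the normalization; the normalization itself is our choice, as the
source toolbox default is unstated). A linear maximum-margin classifier
(SVM, fixed cost 1, configurable) is trained and tested over 10 stratified
cross-validation splits; accuracy is averaged over folds and over 500
resampling runs. Five shuffled-label null distributions of 500 runs each
are built by the identical procedure with labels permuted once per run.
Significance per time point uses the pooled-null empirical one-sided
p-value with add-one correction, `p = (1 + #{null >= obs}) / (1 + N)`,
both raw and Benjamini–Hochberg-adjusted across time points (the add-one
pooled-null formula and the emission of both masks are our choices where
the source is silent).

## The synthetic cohort generator

The generator stands in for the recordings and defines the conditions the
pipeline is exercised under. Behavior alternates exponential inter-press
gaps (mean 8 s) with log-normal hold durations, both snapped to the 10-ms
grid; the default median 1200 ms and log-SD 0.6 at the 1600-ms criterion
give a ~32% success rate and sessions that typically reach 60 rewards in
30–45 minutes — a plausible late-training profile. Rewards follow the
strict-exceedance rule; sessions truncate at 60 rewards or 90 min.

Units are inhomogeneous Poisson processes sampled by thinning. The
instantaneous rate is the baseline rate multiplied by event-anchored
Gaussian gain kernels (press onset, press offset, reward), a U-shaped hold
suppression profile (constant depth with a linear multiplicative ramp up
to a pre-release gain over the final quarter of the hold, mirroring the
firing-rate climb toward release), and an outcome gain over the 1000 ms
after each offset. Gains are multiplicative rather than additive so
down-modulation can never produce negative rates. When several events of
the same kernel fall close together, the kernel contributes its *maximum*
envelope rather than a product over events: stacked events saturate at the
peak gain, which keeps the thinning bound exact. The thinning bound itself
is the profile maximum on a 5-ms grid inflated by 2% (all profile
components vary on scales of tens of milliseconds, so this dominates the
continuous maximum); parameter combinations implying more than 500 Hz are
rejected. Hold suppression can optionally deepen with hold duration
(`depth * exp(-slope * duration_s)`), giving longer presses deeper
suppression when a cohort requires it.

No quantitative firing-rate distributions are available for the recorded
units, so the unit-parameter prior (log-normal baseline around 6 Hz, peak
gains ~1.6–2.4, 30% down-modulated press kernels, outcome gains ~1.6–2.2
after successes vs ~0.8–1.2 after failures) is a free choice stated in the
configuration, not a fact about the data. Group effects are gain
multipliers — default CIE: press-anchored kernels ×1.5, reward-anchored
kernels and outcome gains ×0.5 — encoding the dependence phenotype of
increased press-related and decreased outcome-related OFC activity.
Reproducibility follows an explicit contract: per-unit RNG substreams are
derived from (seed, group, mouse, unit), so enlarging a cohort never
changes previously generated sessions or units, and ground truth records
every effective parameter, sufficient to recompute each unit's exact rate
profile.

What passing tests on this generator do *not* show: real spike trains are
non-Poisson (refractoriness, bursting), correlated within session, and
nonstationary across a session; behavioral learning dynamics and
consumption micro-behavior are absent. Results on synthetic cohorts
validate the *pipeline machinery* — binning, detection calibration,
z-score bookkeeping, decoder calibration and recovery, direction-of-effect
propagation — not the biology.

## Numerical choices and degenerate inputs

* Half-open bins and intervals everywhere; a spike at a boundary belongs to
  the right-hand bin and a spike at a press offset to the post-press epoch.
* Zero-duration presses are forbidden (10-ms floor on the grid).
* All-zero or constant baselines are legal: SD 0 with a degenerate
  percentile interval; z-scores are then 0 at the mean and undefined (and
  flagged) elsewhere.
* Ties in quartile assignment break by press order; remainder presses go to
  the earliest quartiles.
* Decoder folds with a single training class are skipped and logged;
  features with zero training SD are left unscaled (SD treated as 1).
* Empty event classes (e.g. no failures) yield absent PETHs, logged, rather
  than errors.

## Problem sizes used by the test and acceptance runs

The package's own verification runs use deliberately scaled synthetic
cohorts so the full suite completes quickly on one CPU: detector
calibration uses 500 homogeneous 5-Hz units with 100 events each against a
10,000-replicate Monte-Carlo oracle of the identical statistic; detector
power uses 50 units at gain 2.5; decoder calibration uses 6 units over a
long 150-reward session (the large event pool keeps resampling from
latching onto chance biases of individual events) with 150 observed and
5×60 null runs over an 11-point sliding grid; decoder
recovery uses 30 units, 40 events per class, 25 runs and 5×20 nulls; the
direction-of-effect cohort uses 3 mice per group with 4 units each; the
determinism check runs the full pipeline twice at 2 units per mouse with
reduced decoder run counts. Full-scale settings (500 runs, 5×500 nulls,
the full −2,000..+10,000 ms decoding window) remain the package defaults
in `runConfig()`.

## Known limitations

* Pseudo-population decoding discards within-session correlations.
* The up-modulation rule is implemented as consecutive-run, the stricter
  of the two textual readings.
* Quartile boundaries use rank splits, not interpolated percentiles.
* The devaluation normalization formula is read as division by the
  *average* of the two baseline-session response rates.
* Repeated-measures/mixed-model omnibus statistics are out of scope; the
  pipeline exports tidy tables for external statistical tools.
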