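---
title: "Validating actigraphy sleep measures against polysomnography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating actigraphy sleep measures against polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wristwake)
```

## The problem

Wrist actigraphy infers sleep from the absence of movement. Compared with
polysomnography (PSG), accelerometer scoring detects sleep well and wake
poorly: a motionless waking person — reading in bed, or simply trying to
fall asleep — produces the same near-zero activity counts as a sleeping
one. The systematic consequences are an early apparent sleep onset, missed
nocturnal awakenings, and therefore inflated total sleep time (TST) and
sleep efficiency (SE). `wristwake` packages the complete analysis used to
quantify these biases: device scoring, temporal alignment against PSG,
night-level sleep measures under alternative sleep-onset rules, and the
statistics that summarise epoch-level agreement and night-level bias.

## Scoring model

The Cole–Kripke classifier scores each 60 s epoch from a weighted window of
rescaled activity counts spanning the four preceding epochs through the two
following ones:

$$a_j = \min(c_j/\text{scale},\ \text{cap}), \qquad
  D_i = P \sum_{k=-4}^{+2} w_k\, a_{i+k},$$

with the epoch scored *Sleep* when $D_i < 1$. Defaults
(`cole_kripke_params()`): scale 100 (counts), cap 300 (dimensionless after
rescaling), $P = 0.001$, weights $(106, 54, 58, 76, 230, 74, 67)$, threshold
1. These are the 60 s-epoch coefficients in common use for ActiGraph-family
wrist counts. The coefficient dialect differs between scoring
implementations, so all values are parameters rather than constants; results
should always be reported together with the coefficient set used.

Numerical choices:

* **Ties score Wake.** Sleep requires strictly $D < 1$; an epoch exactly at
  threshold is Wake. The boundary case is measure-zero for real count data
  but must be deterministic.
* **Edges are zero-padded.** Windows reaching past either end of the series
  treat missing neighbours as zero counts, preserving the output length.
  Dropping edge epochs was rejected because the Time-in-Bed anchors may fall
  there.
* **Scoring precedes exclusion.** The scorer runs on the full contiguous
  count series; minutes excluded because the PSG was unscorable are masked
  *afterwards*. Exclusion is an analysis filter, not a gap in the signal, and
  the window needs contiguous neighbours.

## Alignment and the Time-in-Bed window

PSG is staged in 30 s epochs; the scorer needs minutes. The first 30 s epoch
of each minute is the minute's representative value. Minute pairing starts
at the first PSG epoch rather than snapping to wall-clock minutes: the
pairing rule needs no clock-alignment assumption, and recordings do not
necessarily start on a minute boundary. A minute whose first epoch is
unscorable is excluded even if its second epoch is scorable, because the
representative value is undefined. Excluded minutes are removed from *both*
streams, shrinking every denominator identically.

Time-in-Bed (TIB) runs from lights-out to the "Awake" anchor — the last
included PSG minute scored Sleep. Terminal wake minutes after that anchor
are outside TIB and contribute to nothing. A lights-out event falling
mid-minute rounds forward to the next minute boundary, avoiding partial
epochs. All sleep measures and (by default) the epoch-by-epoch statistics
are computed over included minutes within TIB; the comparison window is not
uniquely determined by convention, so `confusion()` also offers a
`full_night` scope.

## Sleep measures and onset rules

Sleep onset under rule $k$ is the first minute starting a run of at least
$k$ consecutive Sleep minutes (k = 1, 5, 10 are the conventional choices).
From onset, the measures per night, device and rule are: SOL (Wake minutes
before onset), TST (Sleep minutes from onset through TIB end), WASO (Wake
minutes from onset through TIB end), $SE = 100\,TST/TIB$ and
$SE_{asleep} = 100\,TST/(TIB - SOL)$.

Two definitional points deserve emphasis:

* **TST counts only from onset.** Under a multi-minute rule, isolated Sleep
  minutes before onset belong to no measure; they are surfaced as
  `pre_onset_sleep_min` so the accounting identity
  $SOL + TST + WASO + \text{pre-onset sleep} = TIB$ holds exactly whenever
  onset exists. This is what makes TST vary (slightly) with the rule.
* **SOL counts only Wake minutes** before onset, taken literally; the
  alternative (all minutes before onset) differs exactly by the pre-onset
  sleep count, which is reported, so either convention is recoverable.
* An unscorable gap inside TIB breaks a candidate onset run — the
  conservative choice, since the stream carries no evidence the run
  continued.
* A night with no qualifying run keeps $SE = 0$ and flags $SE_{asleep}$ as
  undefined (`NA`) rather than dividing by a pre-onset-sleep-only
  denominator.

## Validation statistics

**Agreement.** Epoch-by-epoch counts are pooled over all participants'
compared minutes for the headline agreement, sensitivity (fraction of PSG
Sleep minutes the device also scored Sleep) and specificity (fraction of PSG
Wake minutes scored Wake); a per-participant breakdown is returned for
diagnostics. Pooling weights participants by their compared minutes;
participant-averaged rates can be derived from the per-participant table
when equal weighting is wanted.

**Effect sizes.** Cohen's $d$ compares each device/rule cell against the
criterion (PSG under the 1-minute rule) using the independent-samples
pooled-SD form with denominator $n_1 + n_2 - 2$. The data are paired by
participant, but the criterion-vs-comparator framing of classical validation
tables uses the pooled form; the paired form (mean difference over SD of
differences) is available via `paired = TRUE`. Confidence intervals are
bias-corrected percentile bootstrap over participants (resampled jointly to
preserve pairing), 2000 resamples, seeded. Magnitude labels: negligible
$|d| < 0.2$, small to 0.49, moderate to 0.79, large $\ge 0.8$.

**Mixed models.** Per measure,
`value ~ Device * Rule + (1 | participant)` is compared with the
main-effects model by a likelihood-ratio test on maximum-likelihood fits;
the interaction is retained only when $p < \alpha$ (0.05). Estimates and
Wald 95% CIs come from the retained model refitted by REML. Device is coded
with PSG as reference, so the `device_AG` coefficient is the actigraph bias
(positive = overestimation); Rule is coded with 1 min as reference. A
second LRT (main-effects vs. Device-only) tests the Rule main effect. When
the between-participant variance is estimated at zero the fit sits on the
boundary; it is kept and flagged with a warning, since the fixed effects
remain valid.

## What the synthetic cohort emulates

`generate_night()` builds a latent minute-level architecture: a wake run of
the true sleep-onset latency, then a consolidated sleep span interrupted by
a small number of brief awakenings (placed uniformly, non-adjacent, strictly
inside the span, so the night ends on a sleep minute — the Awake anchor),
duplicated into 30 s PSG epochs with optional AASM stage relabelling. Counts
are emitted per minute: wake minutes are *quiet* (near-zero Poisson counts)
with probability `quiet_wake_prob` and restless (gamma counts, mean
`active_count_level`) otherwise; sleep minutes are zero except for
occasional movement bursts. An unscorable PSG block is injected with
configurable probability. Distribution choices — Poisson awakening counts,
shifted-geometric bout durations, gamma count magnitudes — are conventional
forms for bout statistics, stated in the configuration documentation and
overridable. Minute-level (not 30 s) architecture is generated because all
downstream comparisons are minute-resolution.

The `healthy_young_adult` calibration profile fixes the cohort conditions:
480 min in bed, true SOL with mean 19 min (negative binomial, size 4), a
Poisson mean of 3 awakenings of geometric mean length 2 min (sleep
efficiency well above 80%), `quiet_wake_prob = 0.85`,
`active_count_level = 600`, movement bursts of mean 150 counts in 5% of
sleep minutes, and a 15% chance of an unscorable block of geometric mean
20 min. The quiet-wake probability is the dominant control: it produces the
regime this population is known for — very high sensitivity, low
specificity, early apparent onset — and with it the canonical bias pattern
(TST and SE overestimated; SOL and WASO underestimated). The restless-wake
count level matters more than it first appears: very large counts bleed
through the $\pm$4/+2 scoring window into neighbouring minutes, manufacturing
wake detections the device would not really make; 600 is large enough for a
restless minute to score Wake without that artefact dominating.

Cohort heterogeneity comes from jittering the template per participant
(normal TIB offsets, log-normal multipliers on the SOL mean and awakening
rate), which provides the between-participant variance the random intercept
models. Child seeds derive from the master seed as
`(seed + 104729 * ordinal) mod 2147483647`, so a cohort is reproducible from
one integer.

What the generator does **not** emulate: ultradian stage cycling (stage
labels are i.i.d. over sleep minutes), sleep-stage-dependent movement,
positional or device-artefact count structure, circadian drift between
device clocks, and disordered sleep phenotypes. Passing tests on this
cohort therefore demonstrate that the pipeline's computations are correct
and that the qualitative bias mechanism (quiet wake misclassified as sleep)
propagates through all statistics as expected — not that any particular
bias magnitude generalises to a real population.

## Problem sizes and verification

The test suite verifies the scorer against a naive per-epoch window-sum
loop on 1000 random series; checks the onset/accounting invariants on
10,000 random minute sequences; confirms that PSG metrics recovered through
the full pipeline from 200 noiseless synthetic nights equal the generator's
truth bookkeeping exactly; recovers an injected +26 min device bias
(n = 50 participants) within ±2 min with CI coverage; measures the
interaction LRT's false-retention rate over 200 null cohorts of 19
participants; and runs the 19-night calibrated cohort end to end, checking
the direction of every bias and the absence of spurious onset-rule effects.
These sizes keep the whole suite comfortably reproducible on a laptop while
leaving the Monte Carlo checks well-powered.

## Limitations

* Conversion of raw accelerations to activity counts is proprietary and out
  of scope; the pipeline starts from count epochs.
* Only Cole–Kripke scoring is implemented; other classifiers (Sadeh,
  Oakley) and rescoring rules differ enough to need their own validation.
* One sleep period per night is assumed; naps and split nights are not
  handled.
* The pooled agreement statistics weight participants unequally; use the
  per-participant table when that matters.
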