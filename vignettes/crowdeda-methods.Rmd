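---
title: "Methods: electrodermal pipelines for crowd walking experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: electrodermal pipelines for crowd walking experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdeda)
```

## The measurement problem

Electrodermal activity (EDA) — the electrical conductance of palmar skin,
in micro-Siemens — tracks eccrine sweat-gland activity and is therefore an
indirect readout of sympathetic nervous system arousal. In pedestrian
experiments, walkers wear ambulatory sensors sampling conductance at 32 Hz
while their walking speed is manipulated, either directly (a pacer imposes
speeds such as 1.41, 0.86, 0.31 and 0.19 m/s, each walked for 3 minutes)
or indirectly by crowding a closed single-file oval (14.97 m circumference)
with 4 to 40 walkers, so that density dictates speed. The analysis question
is always the same: do per-condition EDA summaries differ systematically
across conditions, within subjects?

`crowdeda` implements that analysis chain end to end — segmentation,
filtering, artifact screening, tonic/phasic decomposition, feature
extraction, design quantities and repeated-measures statistics — together
with a seeded synthetic-cohort generator, so that every stage can be
validated against known ground truth even though raw recordings from such
experiments are typically not redistributable.

## Signal model and decomposition

A conductance trace is modelled as

    y(t) = tonic(t) + (q * h)(t) + e(t),    q >= 0,

where `tonic` is the slowly varying skin conductance level (SCL), `q` is a
sparse non-negative driver of sudomotor bursts, `h` is the biexponential
(Bateman) response kernel `h(t) = exp(-t/tau_d) - exp(-t/tau_r)`, and `e`
is residual noise. The decomposition solves the convex program

    minimize   0.5 * mean((y - B c - A q)^2)
             + lambda_sparsity * sum(q)
             + 0.5 * lambda_smooth * ||D2 c||^2 (scaled per sample)
    subject to q >= 0,

with `B` a cubic B-spline basis on a uniform 10 s knot grid extended
beyond the segment (so the tonic keeps full flexibility at the segment
edges) and `D2` the second-difference penalty, whose null space leaves
constant and linear tonic trends unpenalized. Because `q >= 0`, the L1
term is linear and the program is a smooth bound-constrained quadratic
program. The tonic coefficients are eliminated in closed form and the
driver is found by accelerated projected gradient (FISTA with adaptive
restart), with the step size set by power iteration on the reduced
Hessian. Convergence is declared when the relative objective change over
25 iterations falls below `tol` (default `1e-6`); non-convergence within
`max_iter` raises an error rather than returning a half-solved driver.

Numerical conventions that matter:

* The residual term is averaged per sample while the driver penalty is the
  total driver mass. With the default `lambda_sparsity = 8e-4` this
  soft-thresholds phasic amplitudes by roughly 0.02–0.08 µS depending on
  segment length (about 0.03 µS at 60–110 s, 32 Hz). That is intentional:
  band-limited measurement noise produces trough-to-peak phasic
  excursions of up to ~0.02 µS which would otherwise be counted as
  responses; genuine responses of 0.1 µS and more lose only a few percent
  of their amplitude. Reported amplitudes are therefore mildly
  conservative, uniformly across conditions.
* The sampled kernel is normalized to unit peak, so driver impulse heights
  are phasic peak amplitudes in µS.
* Skin conductance responses (SCRs) are local maxima of the phasic trace;
  the amplitude is measured from the preceding trough (minimum since the
  previous peak). Events with amplitude strictly greater than 0.01 µS
  count as non-specific SCRs (Ns.SCRs). At plateaus the earliest sample is
  the peak, making detection deterministic.

## Filtering and band power

The raw signal is low-passed with a first-order Butterworth at 0.6 Hz,
applied forward and backward so features stay aligned with condition
markers (no phase lag). Two passes square the magnitude response: the gain
at 0.6 Hz is 0.5, not 1/sqrt(2); DC gain is exactly 1. Plain two-pass
filtering rings badly at the ends of a signal sitting at several µS, so
the filter runs on an odd-symmetric, offset-matched extension of the
signal and the core is kept.

The sympathetic band-power index (EDASymp) downsamples the filtered signal
to 2 Hz (anti-alias low-pass at 0.45 times the target rate, zero phase),
removes the mean, estimates the power spectral density by Welch's method
(Blackman window, 128-sample segments, 50 % overlap) and integrates the
PSD over 0.045–0.25 Hz by the trapezoid rule. Units are raw µS² ("area
under the curve"); a total-power-normalized variant is available via
`normalize = TRUE`. The 128-sample window at 2 Hz needs at least 64 s of
signal; shorter segments raise an error rather than silently degrading the
frequency resolution. A sinusoid of amplitude `a` inside the band returns
`a^2/2` within a few percent; out-of-band tones contribute less than 5 %.

## Artifact screening

Ambulatory EDA fails in characteristic ways: electrode-contact loss (zero
lines), saturation (flat lines) and movement spikes. Screening is
rule-based, in the spirit of the wearable-EDA quality literature, with
explicit and overridable thresholds: valid range 0.05–60 µS, maximum
one-sample slope 10 µS/s, flat windows of 5 s with range below 1e-4 µS.
Flat-window detection uses exact sliding windows (O(n) running min/max),
so flagged-sample counts are monotone in the rule parameters. Each flagged
interval is marked accelerometer-coincident when the accelerometer
magnitude within ±2 s exceeds its median + 3 MAD — a robust,
parameter-light burst detector. A recording is excluded when more than
10 % of samples are flagged or any flat/zero run lasts at least 5 s. The
original workflow's second, visual inspection stage is replaced by this
deterministic verdict so that exclusion is testable; the flagged-fraction
threshold is a configuration knob, not a judgement call. Screening runs on
the raw trace, before filtering, because filtering deliberately smears
exactly the sharp features the rules look for.

## Features and baseline standardization

Per subject × condition segment the pipeline reports: mean SCL (arithmetic
mean of the tonic component), Ns.SCR count, mean SCR amplitude (0 when no
events, keeping repeated-measures tables complete), and EDASymp. Segments
are compared on equal footing by truncating every segment of a condition
to the cohort-wide shortest duration, keeping the initial portion.

For mixed models comparing groups, features are z-standardized against the
subject's own resting baseline. A single baseline segment yields only one
value per feature, so the baseline mean and SD are estimated from
non-overlapping 5 s windows of the baseline segment (64 s windows for the
spectral feature, which cannot be estimated on 5 s). Windowed counts are
rescaled to the target segment duration with Poisson scaling (mean by the
duration ratio, SD by its square root). A cohort-level alternative
(standardizing against the baseline-condition distribution across
subjects) is available via `method = "cohort"`; the per-subject windowed
estimator is the default because between-subject baseline differences are
exactly what the standardization must remove.

## Design quantities

For the single-file oval: gross space per person is `circumference / n`
rounded to 2 decimals (round half to even); net space subtracts the average
body depth of 0.288 m from the *rounded* gross value and rounds again.
The round–subtract–round order is deliberate — it is the only convention
that reproduces the published per-occupancy spacing table for all eight
occupancies (for 24 walkers: 0.62 − 0.288 = 0.332 → 0.33, whereas
subtracting first gives 0.34). Net spacing is classified into Hall's
proxemic zones with the conventional metric cut-offs (intimate near/far at
0.15/0.45 m, personal at 0.75 m, social at 1.2/2.1 m, public at 3.6 m,
half-open upper bounds); net rather than gross spacing is used because it
matches the documented zone assignment of every condition. Pacing support
(`marker_spacing`) converts an imposed speed and metronome tempo into
floor-marker spacing (distance covered in two beats).

## Statistical harness

Condition comparisons follow a screen-then-test policy per feature:

1. Each condition cell is screened with a Lilliefors-type
   Kolmogorov–Smirnov test (normal with estimated mean/SD; Monte-Carlo
   p-value with a fixed internal seed, cached per sample size). The
   screening level is 0.05 per cell. With fewer than 5 subjects the screen
   is skipped and the nonparametric branch is taken.
2. If any cell rejects, the omnibus test is the Friedman rank test
   (mid-ranks, tie-corrected); otherwise a one-way repeated-measures ANOVA
   with Greenhouse–Geisser correction (epsilon from the double-centred
   condition covariance, bounded in `[1/(k-1), 1]`, exactly 1 at k = 2).
3. Post hoc, all condition pairs are compared with paired t-tests,
   Bonferroni-adjusted by the number of pairs. Using t-tests (not
   rank-based pairwise tests) after a Friedman omnibus is unconventional
   but mirrors the workflow this package operationalizes; it is
   configurable by calling the pieces directly.

For small tables the Friedman p-value is the exact permutation tail
probability over all within-subject orderings (enumerated when `(k!)^n`
is at most 2000) — the chi-square approximation is visibly off at, say,
4 subjects. Note that the Greenhouse–Geisser correction guarantees
`p_corrected >= p_uncorrected` only in the rejection-relevant regime
(F ≥ 1); for F < 1 the inequality can reverse, which is immaterial for
inference.

Group moderation analyses use a linear mixed model with a random intercept
per subject and fixed effects for condition value, moderator and their
interaction, with Satterthwaite degrees of freedom; a singular
random-effects fit falls back to a fixed-effects model with a warning.
Complete cases only; no imputation — subjects missing any condition are
dropped from the repeated-measures matrix, and excluded segments carry
their exclusion reason instead of imputed values.

## The synthetic cohort generator

`simulate_recording()` builds: a tonic trace (baseline level + linear
drift + per-condition offsets, ramped linearly over 4 s at condition
boundaries so the tonic stays continuous, clipped below at 0.5 µS because
skin conductance cannot reach zero); a phasic component from
Poisson-timed driver impulses convolved with the peak-normalized kernel
(default time constants 0.7 s rise, 2.0 s decay — conventional values for
palmar SCRs); white Gaussian measurement noise; and an accelerometer
channel near 1 g. Event times honour a 1 s minimum spacing *and* keep an
exactly Poisson count distribution: the count is drawn first, then the
times are placed as sorted uniforms on the gap-reduced interval. Injected
artifacts (dropout to 0 µS, flat lines, ≥5 µS spikes) come with
synchronized accelerometer bursts, as genuine motion artifacts do.

Cohort-level defaults emulate the two study designs: per-subject baseline
levels from a normal with mean 6 µS and SD 3 µS truncated at 0.5 µS
(magnitudes resembling published ambulatory ranges, not estimates of any
specific dataset); study 1 as baseline + free walking + four imposed
speeds of 3 min each; study 2 as eight occupancy conditions of 110 s
(the oval runs lasted a little under two minutes). The study-2 generator
plants a monotone tonic gradient across the density ordering with a span
of 2.3 µS by default — the magnitude of the density effect this paradigm
is designed to resolve — and a per-subject, per-condition tonic jitter of
0.8 µS provides the within-subject error that makes repeated-measures
power realistic rather than trivial. Spontaneous SCR rates per condition
are free parameters of the generator (0.1/s by default), not estimates of
any study. A single integer seed is threaded hierarchically
(cohort → subject), so any sub-simulation is reproducible in isolation.

What the generator deliberately does not model: sudomotor physiology
beyond the Bateman kernel, temperature and humidity effects, gait-cycle
coupling into the EDA channel, and realistic accelerometer gait
signatures. Passing recovery tests on this generator therefore shows that
the pipeline is correct and well-calibrated for the signal model above —
not that it is robust to every failure mode of field recordings.

## Validation scale and limitations

The validation suite sizes were chosen to give stable pass/fail behaviour
on a single CPU: SCR recovery over 50 seeded 60 s recordings (about 150
planted events; sensitivity ≥ 0.9, false discovery ≤ 0.1); study-2 power
and type-I over 100 seeded cohorts each (44 subjects × 8 conditions;
the power sweep uses the tonic-level screening mode of `run_cohort()`,
since the planted effect is tonic and the full deconvolution adds nothing
to an SCL contrast except runtime); mixed-model slope recovery over 100
seeded fits of 100 subjects. `scripts/acceptance.R` recomputes all of
these from scratch for any seed.

Known limitations: amplitudes are soft-thresholded by the sparsity weight
(see above), so absolute amplitude comparisons across pipelines with
different weights are not meaningful; the spectral feature needs ≥ 64 s
segments; the exact Friedman enumeration is limited to small tables; and
published test statistics from any particular field dataset cannot be
reproduced without that dataset — the package validates parameter
recovery and error rates instead.
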