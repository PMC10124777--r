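---
title: "Methods: gaze-to-face biomarkers, pupillometry, and their evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-to-face biomarkers, pupillometry, and their evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## 1. The measurement model

A session presents five tasks on a 1920 x 1200 display (65 cm viewing
distance, 1 visual degree = 42 px). Gaze samples `(t, x, y, pupil,
tracked)` are classified against labelled regions of interest. A sample is
*valid* when it is tracked and on screen: off-screen-but-tracked samples are
treated as not acquired on-stimulus, because the stimulus occupies the full
screen and the acquisition metric is defined against presentation time.
Overlapping regions resolve by fixed precedence face > body > activity >
bio > control > validation target > other; face outranks the person regions
it is nested in because gaze to faces is the primary variable.

All derived variables are sample-based dwell proportions; there is no
fixation detection. Percentage-of-time variables use *valid time* as the
denominator, so data loss does not bias them (a property the test suite
checks by doubling dropout). `%Bio` instead uses the preferential-looking
denominator bio/(bio + control) and is undefined on trials where neither
panel was looked at; such trials drop out of the task mean.

Quality control gates at three levels, all boundaries inclusive: trials
(`%Valid Data >= 50`, `Cal Error <= 2.5` degrees, plus reflex-specific
checks for PLR), sessions (administrative invalidation; invalidated trials
stay in the administered denominator), and task-timepoints
(`%Valid Trials >= 25`, both days pooled, because a timepoint comprises both
days). The face composite (OMI) is the unweighted mean of the three task
`%Face` values and is valid only when all three tasks are valid. Cal Error
is aggregated over all trials with an estimate, valid or not: it is an
acquisition metric, not an outcome.

## 2. Pupillometry

The pupil trace model is `B * (1 - c * S((t - t0)/tau))` with `S` the
logistic sigmoid, and the generator shifts `t0` so that the *analytic*
minimum of the second derivative falls exactly at flash + latency (the
logistic's acceleration extremum sits at `u = log((3 - sqrt 3)/(3 + sqrt
3)) ~ -1.317`). Preprocessing removes non-positive samples and jumps larger
than 15% of the median between neighbours, interpolates gaps linearly, and
smooths with a 50 ms centred moving average; traces with under 50% coverage
in the baseline or the 2-s response window are invalid.

Latency is the argmin of the discrete second derivative over the 1000 ms
post-flash window. Estimating that derivative at a single scale cannot work:
a three-point difference is drowned by noise, while a single wide symmetric
kernel systematically shifts the extremum of an asymmetric pulse (about
-13 ms here). The estimator therefore runs a coarse-to-fine cascade of
local-quadratic (Savitzky-Golay) filters with 250, 100 and 40 ms windows,
each stage searching only near the previous stage's estimate. Noiseless
recovery is exact to one sample period across 50-500 Hz and planted
latencies 200-400 ms (tested); under realistic noise a small negative bias
of a few ms remains, shared by both groups, so group *differences* are
essentially unbiased. Constriction is `(baseline mean - trough)/baseline
mean`; the trough is the mean over a +/- 75 ms window centred on the
midpoint of the samples attaining the post-flash minimum, which suppresses
the selection bias of a raw pointwise minimum (bias < 0.01 at 2% noise,
tested) while remaining exact on flat-bottomed closed-form fixtures. Whether
"relative constriction" should use diameter or area is ambiguous in the
pupillometry literature; this package uses the diameter ratio, which is
invariant to rescaling the arbitrary units.

## 3. The synthetic cohort and its calibration

The simulator is a stated world, not a dial: its defaults are the published
cohort conditions (280 ASD / 119 TD, ages 6-11.5, five sites, two
timepoints six weeks apart, two days each, 54 trials/day across AM 4+4, SI
11, SS 6, BM 20, PLR 9, with SS mirrored horizontally on day 2), and its
calibration targets are the published group means/SDs of the primary
variables, the composite effect size 0.788, the six-week ICC 0.836, the
face-memory rank correlation 0.316, the group data-acquisition aggregates
(87.1%/94.0% of trial time; 0.607/0.534 degrees calibration error), and the
PLR latency distributions 285(15)/279(15) ms.

Mechanics, per participant: a logit-scale face propensity per task and
timepoint, `theta = mu + sigma * (sqrt(lambda) * shared + sqrt(1 - lambda)
* unique)`, each component decomposed into trait + state across timepoints.
In-face looking follows a two-state Markov chain with 300 ms mean in-state
dwell whose stationary probability is `invlogit(theta + trial noise)`;
in-face samples are uniform in the face rectangle, others uniform on the
rest of the screen. Tracking loss is i.i.d. per sample at a Beta-distributed
participant rate; a constant per participant-day calibration offset (per-axis
Gaussian, degrees) shifts every emitted coordinate. Clinical scores are
`r * z + sqrt(1 - r^2) * noise` on the standardised within-group T1 face
latent with the Gaussian-copula weight `r = 2 sin(pi rho / 6)`, rescaled to
instrument scales and rounded last.

Three calibration steps connect latents to *realized* downstream values:

1. **Means/SDs.** `(mu, sigma)` per group and task are solved by
   Gauss-Hermite quadrature and Nelder-Mead so that the expected realized
   fraction matches the target, where "realized" folds in the calibration
   offset: face-drawn points survive in the original rectangle with
   probability `rho(v) = (1 - |dx|/Wf)(1 - |dy|/Hf)`, outside points leak in
   with probability `kappa (1 - rho)`, and edge points are pushed off screen
   (out of the valid denominator) with probability `phi`.
2. **Cross-task structure.** The shared fraction `lambda = 0.64` is what the
   published per-task SDs and composite SD jointly imply for the cross-task
   correlation (identically 0.64 in both groups), and it is what makes the
   equal-weight composite's SD come out right.
3. **Stability.** The configured `trait_variance_fraction` is the *realized*
   two-occasion ICC target. Finite-trial measurement noise (closed form for
   a two-state chain: time-average variance `~ 2 p (1-p) tau_c / T`,
   relaxation time `tau_c = dwell * (1 - p)`, plus the delta-method
   trial-noise term) attenuates the downstream ICC, so the latent trait
   share is inflated per group by exactly that predicted variance ratio.

What the generator does **not** emulate: saccade kinematics, stimulus
content, luminance-dependent pupil physiology beyond the sigmoid, site
effects (sites are uniform labels used only as covariate plumbing), age/IQ
relationships with gaze (scores couple only through the face latent), or
attrition between timepoints. A green recovery test therefore establishes
that the pipeline measures what the generative model encodes at the stated
effect sizes — not that the pipeline would reproduce any particular
empirical dataset.

## 4. The evaluation battery

Construct validity uses one-sample t-tests of the TD group at T1 against
area-based chance levels (3.2/8.3/3.9% face-area fractions, 50% for
biomotion), two-sided everywhere except pupil constriction, whose null is
the inequality "no constriction" and is tested one-sided. Stability reports
both two-way ICC variants — consistency ICC(3,1) `(MSR - MSE)/(MSR + MSE)`
and absolute agreement ICC(A,1) `(MSR - MSE)/(MSR + MSE + (2/n)(MSC -
MSE))` — because the source material is ambiguous between them (they differ
only through the occasion main effect); bands are moderate >= 0.5 and high
>= 0.75, with ASD subgroups split at age 8.5 years and IQ 75 (lower bound
inclusive on the upper cell). Group discrimination fits `y ~ group +
covariates` by least squares and tests the group coefficient with a Wald F
against the HC3 covariance (df1 = 1, df2 = n - p), since group variances
are unequal by construction; partial eta squared is reported from the
classical decomposition with group entered last, and Cohen's d from raw
pooled SDs, because robust F and descriptive effect sizes answer different
questions. Clinical correlations are Spearman, with the partial version
computed as partial Pearson on mid-rank-transformed variables (covariates
rank-transformed too) — a choice the package makes explicitly since
"partial Spearman" has no unique definition. No multiple-comparison
adjustment is applied anywhere, matching the descriptive design.

## 5. Numerical choices and degenerate inputs

Boundary conventions: screen bounds are half-open `[0, W) x [0, H)` with
0-based pixel coordinates, origin top-left; emitted coordinates are
truncated (not rounded) to 0.1 px so a boundary sample cannot be pushed off
screen. All QC thresholds are inclusive. Zero valid time makes ROI
percentages `NA` and the trial fails QC; zero between-subject variance
yields non-positive ICCs reported as-is; zero SDs flag infinite t; constant
columns yield missing correlations; rank-deficient designs error naming the
aliased columns. Determinism: one seed in the config drives every draw;
identical config gives byte-identical CSVs (tested via md5).

Scale-downs used by the test suite (stated, not hidden): the recovery
criterion runs 10 seeds of a 160 + 100 cohort at 10 Hz gaze / 50 Hz pupil —
percentage-of-time metrics are sampling-rate invariant and every target is
a population quantity, so reduced scale only widens the Monte-Carlo error
the criterion already accounts for.

## 6. Known limitations

The calibration-error estimate carries the validation-fixation tremor floor
(8 px), so it averages slightly above the planted offset magnitude; it is a
gated acquisition metric, not a recovery target. PLR latency estimates keep
a small common-mode negative bias under noise. The simulator's %Social and
%Activity levels are by-products of uniform off-face gaze rather than
calibrated targets. Empirical acquisition-rate tables, site chi-squares and
the full clinical correlation matrix of the source study are not
reproducible without the restricted raw data, and the package does not
attempt them.
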