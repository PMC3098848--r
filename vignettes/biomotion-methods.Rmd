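---
title: "Models and methods behind biomotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind biomotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomotion)
```

## What the package models

`biomotion` re-implements, as tested and reusable code, the computational
apparatus of a three-part behavioural and fMRI study design of point-light
(PL) biological motion perception, of the kind used to compare schizophrenia
patients with healthy controls:

1. **Masked detection.** Twelve-dot, 1-s PL actions are embedded in
   trajectory-matched noise and presented in a two-interval forced choice
   against their spatially scrambled counterparts; the number of noise dots
   follows a transformed two-up/one-down staircase.
2. **Perturbation discrimination.** Pairs of morphs of the same action,
   always 15 percentage points apart in scrambling (0 vs 15, 15 vs 30,
   30 vs 45, 45 vs 60), are judged for which looks more normal, 40 trials
   per pair, under the method of constant stimuli.
3. **Categorization with event-related BOLD.** Single sequences —
   biological, fully scrambled or 37%-scrambled — are categorized yes/no
   over 216 trials (nine runs of 24, eight per class); behaviour is scored
   with equal-variance signal detection theory, and synthetic BOLD responses
   on a voxel lattice are analysed contingent on the response category
   (hit, correct rejection, false alarm).

No human data ship with the package and none are required: parametric
simulated observers and a synthetic BOLD generator stand in for
participants. Group-level numbers from human cohorts (mean thresholds of
roughly 56 vs 41 noise dots, d′ of 3.82 vs 2.54, and so on) act only as
*calibration anchors* for the observer presets, never as quantities the
package claims to reproduce from scratch.

## Synthetic kinematics

Real PL stimuli come from motion capture, which cannot be distributed here.
The generator instead builds an articulated stick figure: head, torso, and
the elbows, wrists, hips, knees and ankles of four two-segment limbs whose
joint angles follow sinusoids (per-limb mean, amplitude, phase and
frequency), plus torso sway, vertical bounce and a constant whole-body
translation. Fifteen named presets (walking variants, jumps, kicks, throws,
a crouch) span the activity space; `exp2_activities()` fixes the
ten-exemplar subset used by the discrimination design.

Two display constraints are enforced at generation time, matching the
detection display geometry:

* the mean per-dot speed is normalised to exactly **4 deg/s** by a uniform
  rescaling (skipped only for a fully static figure, where no scale can
  achieve it);
* the space–time bounding box must fit a **7 × 7 deg** window centred on
  fixation; parameters whose speed-normalised figure cannot fit are
  rejected as invalid rather than silently compressed, since a second
  rescaling would break the speed constraint.

All sequences use 20 frames at 50 ms. The source conditions state this
frame count only for the categorization experiment; using it everywhere
keeps the morphing algebra on a single timing convention. Actions with zero
translation are exactly periodic: the pose function is a sum of sinusoids
in `t` with the cycle period, so the wrapped frame `T + 1` equals frame 1
to machine precision — a property the tests assert rather than assume.

## Stimulus transforms and their invariant

Scrambling redraws each dot's first-frame position uniformly in a square
window (11 deg for masked stimuli, the 7 deg figure box for morph
endpoints) and replays the dot's original displacement sequence from the
new start. A morph at level λ places every dot at the point dividing
original → scrambled in ratio λ : (1 − λ); because scrambling preserves
displacements this is a per-dot constant translation, so **per-dot
velocities are identical across the original, the scramble and every
morph**. That velocity invariance is the load-bearing contract: it makes
local motion uninformative about global structure, and it implies the
motion-energy index is constant across morph levels of one action (asserted
in the tests).

Noise masking copies complete displacement trajectories from randomly
chosen figure dots (with replacement, no temporal phase offset — the
simplest reading of "same local motion trajectories"), starts them at
uniform positions in the 11-deg window, and wraps positions torus-style at
the window edge so noise density stays constant. The figure itself is
translated by a jitter drawn uniformly from a disc of radius 1.4 deg; the
source conditions state the magnitude but not the distribution, and a
bounded isotropic draw is the least-structured choice. Dot order is
permuted so the figure is not identifiable by index; the permutation is
retained only as an attribute for analysis provenance.

Two non-identical definitions of "motion energy" circulate for these
stimuli — total angular deviation of each dot's direction of motion, and
total path excursion. Both are computed on every call; `angular` is the
default `value`, and neither is treated as ground truth.

## The staircase

The two-up/one-down rule raises the noise level (harder) after two
consecutive correct responses and lowers it after any error, converging on
the level where P(correct)² = 1/2, i.e. ≈ 70.7% correct. Defaults: start
20 noise dots, steps of 6 dots for the first 12 reversals and 3 after,
stop at 16 reversals, threshold = mean of the last six reversal levels,
floor at 0, safety cap 400 trials.

Three bookkeeping conventions are not fixed by the procedure's usual
description and were decided once:

* a **reversal is recorded at the level of the trial on which the movement
  direction changed** (the local extremum), the standard transformed
  up-down ledger;
* the **step-size switch consults the ledger after recording any reversal
  on the current trial**, so it takes effect on the movement that completes
  the 12th reversal;
* the **consecutive-correct counter resets on every level movement**,
  which also makes "you must get the first two trials right to leave the
  starting level" an emergent property rather than special-case code.

A scripted correct–correct–error cycle then has a closed-form trace —
reversals alternate 26/20 for the big-step phase and 23/20 after the
switch, giving a last-six ledger of [26, 20, 23, 20, 23, 20] and a
threshold of exactly 22.0 — which the tests assert verbatim. Against a
smooth simulated observer the mean probability correct at the estimated
threshold, over 500 independent staircases, lands near 72%: about a point
above the asymptotic 70.7%, the familiar small-sample bias of short
transformed staircases with asymmetric steps, and inside the ±2-point band
the acceptance suite checks.

## Simulated observers

* **Detection**: P(correct | n) = ½ + (½ − lapse)·exp(−(n/α)^β), a
  decreasing Weibull-type function of noise-dot count. Presets put the
  70.7% point at 56 (control) and 41 (patient) noise dots via
  α = level / (−ln r)^(1/β).
* **Discrimination**: each sequence yields internal coherence
  gain·(1 − λ)^exponent + Gaussian(0, σ); the observer picks the larger
  sample, so P(choose less perturbed) = Φ(Δc / (σ√2)). The exponent
  (default 4 in the presets) makes equal 15-point differences harder at
  higher base perturbation, reproducing the declining group accuracy
  profiles; the patient preset lowers gain (reduced sensitivity to
  perturbation). A compressive transform of perceived perturbation is the
  alternative mechanism discussed for patient behaviour; lower gain is the
  default because it reproduces the observed pattern (chance by the
  30-vs-45 pair) directly.
* **Categorization**: equal-variance SDT; evidence ~ N(0, 1) for
  scrambled, N(d′, 1) for biological, N(frac·d′, 1) for intermediate;
  respond "biological" above a criterion. Presets: d′ = 3.82 / 2.54 with
  criteria placed to give false-alarm rates near 20% / 38%.

One calibration anchor is unattainable in this model family and is left
so deliberately: the reported proportion of "biological" responses to
37%-scrambled sequences (4% controls, 19% patients) is *lower* than the
same groups' false-alarm rates to fully scrambled sequences. A
single-criterion equal-variance observer with intermediate evidence mean
frac·d′, frac ≥ 0, always produces an intermediate rate at least as high
as its false-alarm rate. The default `intermediate_mean_frac = 0` therefore
makes intermediate trials behave exactly like scrambled ones, preserving
the group *ordering* (patients respond "biological" more often) but not the
printed absolute rates; matching those would require a second criterion or
unequal variances, which the emulated analysis does not use.

All observer decisions go through a counter-based generator
(`counter_uniform()`, a splitmix32 hash of seed and trial index), so the
draw for trial k depends only on (seed, k): reordering trials or inserting
diagnostics can never silently change simulated behaviour. Cohorts add
optional log-normal between-subject variation (CV 0.15 by default, a
typical inter-subject spread for psychophysical sensitivity parameters).

## Behavioural statistics

d′ = z(H) − z(F) and c = −(z(H) + z(F))/2, with the log-linear
(add-0.5 / add-1) correction by default — mandatory here because calibrated
control observers produce hit rates near 1 on 72 signal trials. The
correction has a known cost: at d′ = 3.82 with the liberal preset
criterion, the expected estimate over 216-trial sessions is shrunk by
about 0.55 (computable exactly by summing the binomial pmf), so the
parameter-recovery suite places the criterion at d′/2, where both rates
stay clear of saturation and recovery is unbiased to within 0.05 for
d′ ∈ {1, 2.54, 3.82}. Recovery within ±0.1 is a property of the estimator
at a reasonable operating point, not of the saturated preset.

The above-chance criterion is the smallest k with exact one-sided tail
P(X ≥ k | n, p0) < α — 26 of 40 at α = 0.05 — verified in the tests
against brute-force summation for all n up to 100. Cohen's d from group
summaries recovers SDs as se·√n and pools them; on the false-alarm summary
statistics this gives ≈ 0.71, whereas the value computed from individual
data in the emulated study is 0.75 — the summary-based number is an
approximation and is documented as such. The association tests are the
textbook statistics (Pearson χ² without continuity correction,
pooled-variance t); one reported χ² of 4.41 for an 8-of-12 vs 5-of-15
split is not reproduced by the textbook formula (which gives ≈ 2.97), and
the package implements the textbook statistic without attempting to
reconcile the discrepancy.

Per-activity accuracy pools all perturbation pairs except the most extreme
(45 vs 60), where the task is at chance for everyone.

## Synthetic BOLD and the ROI analysis

The simulator places one ellipsoidal "responsive region" (default ≈ 60
voxels, inside the 15–174-voxel range the localizer analysis is expected
to produce) in a 20 × 20 × 10 lattice. Each region voxel's series is
baseline × (1 + (signal + noise)/100): the signal superposes, per event, a
condition amplitude times a unit-peak response (1-s boxcar convolved with
a double-gamma HRF), so amplitudes are interpretable directly as peak
percent-signal changes; the noise is stationary AR(1) (SD 0.5% of
baseline, lag-1 correlation 0.3) with white innovations, independent
across voxels. Event designs use TR 2 s, 1-s stimuli and an 11-s ISI;
block designs use 14-s alternating blocks (7 per condition for the
biological-vs-scrambled localizer, 14 for motion-vs-static).

The analysis chain mirrors the emulated study:

1. **GLM**: OLS per voxel on intercept plus one convolved regressor per
   condition; two-sided p from the t distribution. Rank-deficient designs
   are an error naming the collinear columns. Under white noise the null
   p-values are uniform (checked by KS test); under the default AR(1)
   noise OLS p-values are mildly miscalibrated, as in any analysis that
   ignores temporal autocorrelation — the null-calibration checks
   therefore use white noise.
2. **ROI definition**: Benjamini–Hochberg step-up at q = 0.05 over all
   voxels; if nothing survives, re-threshold at uncorrected p < 0.003;
   then keep the largest 6-connected component, ties broken by higher mean
   |t|; an empty set after the fallback is flagged "not localizable"
   rather than invented. Connectivity and tie rules are not specified by
   the emulated analysis ("contiguous voxels"); 6-connectivity is the
   conservative standard.
3. **Event-related averaging**: each voxel's series is converted to
   percent change about its own run mean, averaged over the ROI, cut into
   onset-aligned epochs (onset sample to 12 s) and averaged per condition.
   A condition with no events is an error, mirroring the exclusion of
   empty response-contingent categories (misses, sparse intermediate
   "biological" responses).
4. **Peak percent change**: maximum over post-onset samples within 10 s
   (before the next trial's warning cue) minus the value at the onset
   sample, read from the raw averaged values with no HRF fitting. The
   baseline is the single onset sample; whether any pre-onset averaging
   was used in the emulated analysis is unstated, and the single-sample
   contract is adopted.

The end-to-end property the acceptance suite checks is qualitative, as the
group finding is: a control-like amplitude map (hit ≈ false alarm >
correct rejection) yields analysed peak orderings with that shape, and a
patient-like map (all conditions equal) yields no separation, in over 95%
of seeds.

## Problem sizes and runtime choices

Monte-Carlo sizes were fixed once at desk scale: 500 staircases for
convergence and threshold recovery, 1000 sessions per generating d′ for
recovery, 100 seeds for the FDR oracle and null calibration, and 20 seeds
per group (three-run sessions on a 10 × 10 × 5 lattice) for the
end-to-end imaging property. These sizes put Monte-Carlo standard errors
well inside each criterion's tolerance; larger designs change nothing but
the wait.

## What passing tests do and do not show

The synthetic modules emulate the *structure* of the study — designs,
trial counts, stimulus geometry, response-contingent conditioning — and
observers whose group-level behaviour lands near the calibration anchors.
They do not emulate motion-capture kinematics, learning or lapse dynamics,
scanner artefacts, spatial noise correlation, or between-voxel amplitude
heterogeneity. Green tests therefore certify the pipeline's arithmetic and
its statistical conventions, not any claim about real observers; the one
place where the model family provably cannot match an anchor (intermediate
response rates below false-alarm rates) is documented above rather than
patched.
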