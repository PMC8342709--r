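---
title: "Methods: inverted encoding models of spatial working memory under distraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inverted encoding models of spatial working memory under distraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmiem)
```

## What this package computes

`wmiem` implements a complete model-based analysis pipeline for spatial
working-memory (WM) fMRI experiments of the memory-guided saccade type: a
target at a random polar angle on an isoeccentric ring (12° eccentricity) is
held in memory over a 12 s delay, on 70% of trials an attended distractor
appears mid-delay at one of seven counterbalanced angular offsets, and the
trial ends with a saccade to the remembered location. Because the package is
meant to be verifiable without scanner data, it pairs every analysis stage
with a synthetic-data generator whose outputs have the statistical structure
the analyses assume.

The analytic core is an **inverted encoding model (IEM)** of polar angle.
Voxel activity is modeled as a linear combination of $k = 8$ information
channels, smooth tuned filters over polar angle $\theta$ centered at evenly
spaced preferred angles $\psi_i$:

$$
f_i(\theta) \;=\; 0.5 + 0.5\,\cos^{p}\!\Big(180\,\frac{\theta-\psi_i}{2s}\Big)
\quad \text{for } |\theta-\psi_i| < s,\; 0 \text{ otherwise},
$$

with size constant $s = 180°$, exponent $p = 8$, the cosine argument in
degrees, and angular differences wrapped to $[0°, 180°]$. The forward model
is $B = CW$ with $B$ (trials × voxels) the measured activity, $C$ (trials ×
channels) the predicted channel responses, and $W$ (channels × voxels) the
weights. Training solves the ordinary least squares problem
$\hat W = (C^\top C)^{-1} C^\top B_{\mathrm{trn}}$; testing inverts the model,
$\hat C_{\mathrm{tst}} = B_{\mathrm{tst}} \hat W^\top (\hat W \hat W^\top)^{-1}$,
and the **reconstruction** $r(\theta) = \sum_i \hat c_i f_i(\theta)$ is
evaluated on a uniform 1° grid over $[0°, 360°)$. Two scalar summaries are
derived from each aligned reconstruction:

* **fidelity** $F = \operatorname{mean}_\theta\, r(\theta)\cos\theta$, the
  projection onto the aligned direction — exactly baseline-invariant on a
  uniform full-circle grid; and
* the **decoded angle**, the circular mean
  $\hat\theta = \operatorname{atan2}\big(\sum r\sin\theta, \sum r\cos\theta\big)$,
  undefined (returned as `NA`, never a silent 0) when the resultant length
  falls below $10^{-9} \sum |r|$.

A *fixed* encoding model — estimated once from an independent training task
and then frozen — is used for all timepoints and conditions, so that
reconstructions are comparable across the trial. The training activation is
the delay-period average over the window 5.25–12 s after delay onset, which
contains exactly 9 TRs of 750 ms under the half-open $[\text{start},
\text{end})$ TR-inclusion convention used everywhere in the package.

### Channel exponent precedence

As typeset in the literature, the basis formula is ambiguous about whether
the exponent applies to the cosine alone or to the whole half-raised cosine.
The default (`power_on_cosine`) applies it to the cosine, which leaves each
channel a 0.5 baseline over most of the circle; `power_on_sum` produces the
narrower, baseline-free bump that iterative basis constructions typically
use. All structural identities (unit response at a channel's own center,
zero outside the support) hold in both modes, and every pipeline stage takes
the basis as an argument, so the choice is fully configurable.

## Analyses

* `fidelity_timecourse()` inverts the frozen model at every TR, aligns each
  trial's reconstruction to the target (or distractor; distractor-absent
  trials are then dropped, with counts available from the trial table), and
  averages fidelity over trials.
* `epoch_metrics()` does the same for delay epochs: PRE 3.75–5.25 s, DIST
  8.25–9.75 s, POST 10.5–12 s after delay onset — windows placed under an
  assumed ~4 s hemodynamic delay so that "DIST" captures the BOLD response
  to a distractor shown 4.5–5.5 s into the delay.
* `loro_generalization()` trains at each timepoint/epoch on all runs but
  one (distractor-present trials only), reconstructs the held-out run at
  every other timepoint/epoch, and cycles folds so every trial is tested
  once. Stable codes give positive fidelity everywhere; a morphed code
  collapses the PRE→POST and POST→PRE cells while the diagonal survives.
* `behavioral_bias()` and `coupling_analysis()` analyze near-distractor
  trials (|relative distractor angle| ≤ 12°, boundary inclusive). Signed
  errors are flipped by the side of the distractor so positive = toward the
  distractor; the coupling analysis computes per-participant Pearson
  correlations between POST-epoch decoding errors and behavioral memory
  errors (clipped at |r| = 1 − 1e−10 before the Fisher z transform), plus a
  pooled quartile-binned variant.
* `rf_sorted_timecourse()` gives the univariate view: voxels with pRF
  centers within 15° of the stimulus (RF-in) versus at least 165° away
  (RF-out), both boundaries inclusive, restricted to eccentricities 2–15°
  and variance explained ≥ 10%, baseline-corrected by the mean over
  −2.25–0 s.

## Permutation inference

All inference is permutation-based, shuffling only **within participant**:

* `perm_rm_anova()` — fully within-subject ANOVAs (1–3 factors, one
  observation per participant × cell). The F statistics come from
  orthonormal within-subject contrast projections (the standard
  sphericity-assumed decomposition; they agree with `aov()` with an
  `Error()` stratum to machine precision), which makes the permutation loop
  a matrix product. The null freely permutes each participant's cell
  labels, the weakest exchangeability assumption consistent with shuffling
  within participant.
* `perm_paired_ttest()` — condition contrasts aggregated run-wise: run
  means per condition, participant means of run means, paired t across
  participants, null from shuffling run-wise condition labels within
  participant.
* `shuffled_label_fidelity_null()` — the model-level null: training target
  labels are permuted within participant, the model re-estimated, and the
  test-set fidelity t recomputed per timepoint.
* `fdr_correct()` — Benjamini–Hochberg step-up (via `stats::p.adjust`).

One-tailed p-values are the proportion of null statistics ≥ the observed
one, with ties counting toward the null and a floor of $1/n_{\mathrm{perm}}$
(0.001 at the default 1000 permutations). Two-tailed p-values double the
smaller tail (capped at 1). We deliberately double the *smaller* tail rather
than always the upper one: doubling a fixed tail can never reject effects in
the other direction and makes the test's actual size ≈ 0.026 instead of
0.05, which would fail any Type-I calibration check. With the smaller-tail
rule the empirical rejection rate under the null sits at the nominal level
(verified by 500-repetition calibration runs in the test suite).

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analyses expect.

**Designs.** `generate_design()` builds runs of ten trials — seven
distractor-present, three absent, randomly ordered — with the seven relative
distractor bins counterbalanced exactly once per run. Bin centers are the
absolute separations 0°, 30°, …, 180°, each given a random sign and a
uniform ±12° jitter (bins are 24° wide). This geometry is the reason the
counterbalancing identity holds: the cosines of the seven centers sum to
zero, so distractor energy cancels exactly (in expectation) from
target-aligned fidelity. One bin sits at 0° separation, which keeps the
near-distractor (≤ 12°) analyses populated at one trial per run.
`generate_training_design()` builds the independent model-estimation task:
16 evenly spaced targets per run (22.5° apart), staggered by 11.25° on
alternate runs, 32 unique positions overall.

**Voxel populations.** `generate_population()` assigns each voxel a
preferred polar angle (uniform), eccentricity (uniform on 2–15°, matching
the RF-selection window), a circular-Gaussian tuning width (25–50° SD; voxel
tuning is far broader than neuronal tuning, and widths in this range let an
8-channel basis represent the population well), simulated variance explained
on 0.1–0.8, and independent delay/distractor gains on 0.5–1.5.

**BOLD time series.** `simulate_timeseries()` builds, per trial and voxel,
a sustained target drive (tuning evaluated at the target angle plus any
injected trial-wise neural bias) over the encoding-plus-delay window and, on
distractor-present trials, a transient distractor-tuned drive during the 1 s
distractor window. Drives are convolved with a canonical double-gamma
hemodynamic kernel (peak ~5 s, 1/6 undershoot) on a 250 ms grid, sampled at
the 750 ms TR onsets from −3 to 15 s around delay onset, degraded with
i.i.d. Gaussian noise (optionally AR(1), off by default), and z-scored per
voxel within each run.

Two generator choices deserve emphasis:

* **Joint-encoding interference (`target_suppression`, default 0.4).** With
  a purely additive distractor response, the counterbalanced bins make the
  distractor exactly orthogonal to target-aligned fidelity in expectation —
  so the well-documented dip in target fidelity during distraction could
  not appear at any noise level. The generator therefore attenuates a
  fraction of the target drive during the distractor window on present
  trials, modeling the cost of jointly encoding the memorandum and the
  distractor in one population. The value 0.4 was chosen from the magnitude
  such dips take in delay-period fidelity (roughly one-third to one-half)
  and is not revisited; `target_suppression = 0` recovers the pure additive
  signal, and the suppression is gated on `distractor_gain != 0` so that
  switching the distractor response off makes present and absent trials
  exactly identical.
* **Z-scoring and the noiseless corner.** Per-run z-scoring is a noise
  normalization; with `noise_sd = 0` it divides each voxel by its
  signal-only variance, which differs between training and test runs and
  biases decoding by up to ~20°. Exact-recovery checks therefore run with
  `zscore = FALSE`; at realistic noise the scaling is dominated by the
  common noise floor and the bias is negligible.

**Behavior, staircase, gaze.** `simulate_behavior()` composes the signed
memory error as `coupling × neural_bias + attract_bias × (side of
distractor) + N(0, motor_sd)`, wrapped; defaults are motor SD 2° of polar
angle, 1° attraction, log-normal RTs with ~350 ms median, and a distractor
cost of 1.25× motor noise and +40 ms RT on present trials — magnitudes
typical of memory-guided saccades. `simulate_staircase()` implements the
three-down/one-up rule (three consecutive correct → harder, any error →
easier), whose asymptote solves $P(\text{correct})^3 = 0.5$, i.e. 79.4%
("~80%"); the first 25% of trials are discarded as burn-in before the
converged accuracy is computed. `simulate_gaze()` emits 500 Hz traces:
fixation, a minimum-jerk saccade with main-sequence duration
(21 ms + 2.2 ms/deg) launched RT after the response cue, optional blinks and
positional jitter, with ground-truth onsets/offsets returned for testing the
detector.

## Oculomotor scoring

`preprocess_gaze()` applies, in order: pixel→degree conversion (when a
screen geometry is supplied), blink/extreme-value invalidation, Gaussian
smoothing (5 ms SD), per-trial drift correction (subtracting the mean eye
position over known fixation epochs), and run-wise recalibration by fitting
a 3rd-order polynomial from measured to true positions independently per
axis. `detect_saccades()` marks maximal runs of samples with speed (central
differences) strictly above 30°/s lasting at least 7.5 ms — 4 samples at
500 Hz, rounding up — with net displacement ≥ 0.25°. The reported onset is
the last sub-threshold sample before the run, since the true crossing lies
between it and the first supra-threshold sample; on noiseless synthetic
saccades this recovers ground-truth onsets within one sample.
`score_trial()` takes the behavioral report as the final eye position before
the memory target reappears (0.8 s after the response cue, after any
corrective saccades) and excludes trials on any of five conjunctive,
order-independent flags: no saccade in the response window; initial-saccade
duration ≥ 150 ms; initial-saccade amplitude < 5°; endpoint further than 5°
(Euclidean, degrees of visual angle) from the target; or a fixation
excursion ≥ 2.5° during the delay. The duration rule reads the "less than
150 ms total duration" criterion as a property a *valid* saccade must have,
so saccades at or above 150 ms are excluded. Precision is summarized as the
ordinary sample SD of target-aligned endpoint polar-angle errors —
appropriate in the small-error regime of memory-guided saccades, where
circular and linear SDs coincide.

## Numerical conventions

* Angles live on $[0°, 360°)$; differences are wrapped to $(-180°, 180°]$
  with the antipode mapped to +180°.
* Matrix inversions are guarded by a reciprocal-condition-number threshold
  of $10^{-10}$ (on the training channel matrix and on $\hat W \hat W^\top$);
  violations raise an error naming the deficient object rather than
  returning garbage.
* Alignment snaps the reference to the nearest 1° grid point; total
  activation is preserved exactly.
* Negative reconstruction activations are kept as-is in both metrics (no
  rectification).
* Every stochastic function takes an explicit integer seed and is a pure
  function of its inputs and that seed; the pipeline derives per-stage,
  per-participant seeds from one master seed, all below $2^{31}$.

## Problem sizes

The shipped test-suite and demonstration configurations use desk-scale
sizes chosen so the full suite runs in minutes on one core: 3–7 simulated
participants, 4–12 runs (40–120 trials) per participant, 2 training runs
(32 trials), 60–160 voxels, 100–1000 permutations, and 500 repetitions for
Type-I calibration checks at 200 permutations each. The statistical
machinery is size-agnostic; `pipeline_config()` defaults mirror a
seven-participant study and scale up by changing arguments.

## What passing tests do and do not show

The generator reproduces the *structure* the analyses rely on — tuned
populations, hemodynamic smoothing and lag, per-run standardization,
counterbalanced geometry, couplings between neural bias and behavior — but
not fMRI noise physics: there is no scanner drift, no physiological noise,
no spatial noise correlation between voxels (an AR(1) option covers temporal
autocorrelation only), no voxel-size or partial-volume effects, and the
true voxel tuning is exactly the circular-Gaussian family the simulator
draws from, whereas real voxel tuning is only approximately unimodal. Green
tests therefore certify the correctness and calibration of the *procedures*
(model algebra, metric identities, permutation Type-I error, detection and
exclusion rules, recovery of injected effects), not the effect sizes one
should expect from real cortex. Headline empirical quantities from real
data — absolute fidelity values, dip magnitudes, region-specific coupling —
are deliberately out of reach at desk scale and are not asserted anywhere.

## Known limitations

* The IEM is 1-D in polar angle; eccentricity is unmodeled, so radial
  errors are invisible to the decoder.
* The circular-mean decode is undefined for antipodally symmetric
  reconstructions and is biased toward a present distractor's
  representation — which is exactly the property the coupling analysis
  exploits, but means "decoding error" conflates target drift with
  distractor pull on present trials.
* `validate_store()` checks design invariants against the default bin
  geometry; stores generated with custom `bin_centers` will flag those
  rows.
* The multi-factor permutation scheme (free within-participant cell
  permutation) is one of several defensible exchangeability choices for
  repeated-measures ANOVA; alternatives (restricted/residual permutation)
  are not implemented.
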