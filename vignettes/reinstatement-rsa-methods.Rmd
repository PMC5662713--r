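---
title: "Measuring memory reinstatement with searchlight RSA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring memory reinstatement with searchlight RSA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinstatr)
```

## The scientific question

When an episodic memory is retrieved, the spatial pattern of brain activity
that was present when the event was encoded is thought to be reinstated.
`reinstatr` implements the full analysis stack for testing this with
functional MRI in a design where subjects watch a set of short videos
(encoding, *Enc*), silently retrieve them minutes later (immediate
retrieval, *ImRet*, split over two scanner runs on Day 1), and retrieve
them again a week later (delayed retrieval, *DelRet*, one run on Day 8).
Reinstatement is operationalized with representational similarity analysis
(RSA): for a pair of phases, the Pearson correlation between the per-trial
activity patterns of the *same* video should exceed the correlation between
patterns of *different* videos.

The package covers per-trial pattern estimation (first-level GLM), the RSA
contrast machinery, volumetric searchlight and ROI statistics, inter-subject
pattern correlation, permutation-based group inference, behavioral scoring
statistics, and a synthetic-study generator that makes every stage testable
with known ground truth.

## Per-trial pattern estimation

Each run is modelled with one HRF-convolved boxcar regressor per trial of
interest (encoding and retrieval trials with their actual durations), one
2 s regressor per retrieval cue — estimated, but never entered into RSAs —
plus no-interest regressors: the vividness-rating events, six motion
series, a global white-matter drift series (the per-volume mean of
voxelwise z-scored white-matter time courses), and an intercept. A Day-1
run therefore carries 36 regressors of interest (12 Enc + 12 ImRet + 12
cues) and the Day-8 run 48. The first five volumes of each run are
discarded. The drift regressor takes the place of high-pass filtering so
that slow effects spanning the encoding and retrieval blocks of a run are
not filtered away.

The trial pattern is the per-voxel t statistic `beta / SE(beta)` from an
ordinary least-squares fit, with residual degrees of freedom
`volumes - columns`. Two deliberate simplifications, chosen because the
t-maps are used only *relationally* (through correlations across voxels):
no autocorrelation (AR) correction, and no slice-timing offsets in the
synthetic data. The residual variance is floored at `1e-12` so that
noise-free simulations yield beta-proportional maps rather than 0/0.

A cue-control variant (`retrieval_variant("exclude_first_12s")`) re-times
every retrieval regressor to `[onset + 12 s, offset]` and models the
excluded 12 s with a separate no-interest column, so that any
reinstatement effect attributable to the visual cue is absorbed. Modelling
the excluded window explicitly (rather than leaving it unmodelled) was a
design choice: it keeps the residual degrees of freedom honest and
prevents cue-evoked variance from contaminating the baseline. The rating
nuisance event is modelled at the end of each retrieval trial with a
4 s default duration (`rating_duration`), a configuration knob since its
exact parameterization is not critical.

## RSA contrasts

Both contrast kinds are zero-sum trial-pair weight matrices over the
Fisher-transformed correlation matrix `z_ij = atanh(corr(a_i, b_j))`
(clipped at `1 - 1e-7`):

* **Same-versus-different** — `+1/N_same` on same-video pairs, `-1/N_diff`
  on different-video pairs, so the statistic is
  `mean(same z) - mean(diff z)`. For Enc/ImRet, where both phases live in
  the two Day-1 runs, between-run pairs are excluded to keep run effects
  out of the contrast; with the 2 × 12 design this leaves exactly 24 same
  and 264 different weighted pairs. Phase pairs involving DelRet have no
  exclusions (24 same, 552 different). A raw-sum mode
  (`normalize = "sum"`) reproduces the summed-difference form, which for a
  constant design is a fixed positive multiple of the mean form and leaves
  one-sample group inference invariant — the mean form is the default for
  interpretability.
* **Weighted diagonal** — nonzero weights only on same-video pairs, equal
  to the video's score minus the mean score across the subject's videos
  (zero-sum by construction). With relative memory scores (per-video
  across-subject centring, `relative_performance()`) as input, the weights
  are effectively doubly centred; adding a constant to a subject's scores
  provably cancels out. If all videos were reinstated equally the contrast
  is identically zero.

Because every weight matrix sums to zero, any constant added to all
z values — scanner-wide similarity, baseline pattern overlap — drops out of
both statistics.

## Searchlight and ROI statistics

The searchlight at centre v comprises all in-mask voxels within a
Euclidean radius of 3 voxel units (123 lattice points in an unbounded
mask, fewer at mask edges; ties at exactly the radius included). The
weighted sum of Fisher-z correlations over that neighborhood is assigned
to v. Centres with fewer than `min_voxels = 10` in-mask neighbours return
`NaN` — the design is silent on edge behaviour, and the floor prevents
degenerate correlations on a handful of voxels. A pattern with zero
variance inside a neighborhood contributes z = 0 to its pairs and is
counted (rather than propagating `NaN`), keeping maps defined. Distances
are measured in voxel-index units, isotropic; the 0.6 mm inter-slice gap
of the acquisition this emulates is ignored.

The engine is compiled (C++) and is verified in the test suite against an
independent brute-force R implementation at every voxel of a toy grid, for
all three phase pairs and both contrast kinds, to `1e-10`.

ROI statistics treat all ROI voxels as a single pattern. For the
same-versus-different contrast the two averages (same z, different z) are
returned separately and compared downstream with a paired t test; whether
the ROI averages should mirror the searchlight's Day-1 between-run
exclusion is not fixed by the design, so the default mirrors the weight
matrix. ROI sphere voxels outside the analysis mask are excluded
(in-mask-only neighborhoods, the default for the searchlight too).

## Inter-subject RSA

Patterns are first smoothed with a 6 mm FWHM Gaussian
(`sigma = fwhm / 2.355` per axis, converted to voxels; mask-renormalized
so edge voxels are not diluted), then each subject's phase-A pattern for a
video is correlated with the leave-one-out average of all other subjects'
phase-B patterns for that video, with the same searchlight and weight
machinery as the within-subject analysis. Smoothing precedes averaging.
The same-versus-different weighting is used by default (the inter-subject
analysis is described as otherwise identical to the within-subject one);
since run assignment of videos differs across subjects, the Enc/ImRet
between-run exclusion is taken from the reference subject's tables — an
arbitrary but harmless convention in the synthetic setting, noted here for
real-data use. Synthetic data live on one common grid, so group-space
normalization is a no-op; a resampling hook would be needed for real data.

## Group inference

Subject maps are combined with voxelwise one-sample t tests against zero
(`df = n - 1`), or paired t tests on difference maps for comparisons
between phase pairs. Cluster-extent family-wise error correction uses a
**sign-flip permutation** null instead of random-field theory: clusters are
formed at the cluster-defining threshold p < 0.001 (one-tailed positive
for predicted-positive reinstatement maps; two-tailed for paired
comparisons, where both directions are of interest), and the null
distribution of the maximum cluster size is obtained by randomly flipping
the sign of whole subject maps (exact enumeration when `2^n` does not
exceed the permutation budget). The corrected p of a cluster of size k is
`(1 + #{permutation maxima >= k}) / (n_permutations + 1)`, with the
identity flip always included — a valid, slightly conservative estimator.
Sign-flipping is exact under a symmetric null and distribution-free, which
a simulation-first package can actually verify: the suite runs 200
replicate null studies and checks that the family-wise false-positive rate
lands inside the binomial 95% CI of the nominal 0.05. Cluster connectivity
defaults to 18 (faces + edges), with 6 and 26 selectable. Supplying an ROI
restricts both thresholding and the permutation maxima to the ROI
(small-volume correction).

The 2 (correlation type: same, different) × 3 (phase pair) comparison in
the ROI is a fully within-subject repeated-measures ANOVA; the interaction
F is reported with degrees of freedom computed from the data,
`(2, 2(n - 1))` for complete data — e.g. (2, 40) at n = 21, (2, 38) at
n = 20.

## The synthetic generator

`generator_config()` encodes the study conditions: 21 subjects, 24 videos
(durations uniform on 29–48 s), Day-1 split of 2 runs × 12 videos plus a
Day-8 run of all 24, TR 2.62 s, 12 s inter-stimulus fixation, 2 s cues,
self-paced retrieval truncated to the 20–55 s window (means 35.1/33.6 s,
SDs 8.0/8.8 for immediate/delayed), free-recall detail scores with mean
11.5 and SD 2.7 in half-point steps, immediate vividness mean 4.2 on the
1–6 scale dropping by 0.7 after a week.

The latent pattern model gives analytic control of the effect size. Each
video has a unit-variance Gaussian latent pattern over the effect region;
a subject's observed trial pattern there is
`a * latent + sqrt(1 - a^2) * noise`, so the expected same-video
correlation between phases p and q is `a_p * a_q`, and the per-phase
loadings are solved from the requested same-minus-different Fisher-z gap
via `corr = tanh(z)` (three pair targets give a log-linear 3 × 3 system;
an implied correlation at or above 1 is rejected as impossible). Outside
effect regions patterns are pure noise. Monte-Carlo validation (100
replicate seeds in the suite) confirms the empirical group-mean gap
matches the requested `delta_z_same` well within 20%.

Two further knobs tie the generator to the study's secondary analyses:

* `behavior_coupling` — the per-video same-pair z target becomes
  `delta + coupling * (relative score)` (implemented as a joint scaling of
  all phase loadings so the three pair targets stay mutually consistent),
  so reinstatement strength rises with relative memory performance with a
  known slope; scores are drawn first and drive the patterns. The shifted
  target is clamped at zero, so couplings large relative to
  `delta / SD(score)` truncate the left tail and inflate the realized mean
  gap; at the study-condition gap of ~0.03 Fisher-z the default coupling
  of 0.01 per detail point keeps this clamping negligible while leaving
  the weighted contrast clearly detectable at n = 21.
* `shared_fraction` — the fraction of each video's latent shared across
  subjects (`sqrt(f) * common + sqrt(1 - f) * private`), which controls
  inter-subject pattern correlation without affecting within-subject
  statistics.

Vividness ratings are generated around the study means with a per-subject
offset (SD 0.35), a within-subject slope of 0.25 per standardized detail
score plus rating noise of SD 0.5 (implying a within-subject
vividness-performance correlation near 0.45), and a per-subject drop drawn
with SD 0.40 (so the SD of mean paired differences is near 0.42, matching
a drop t statistic in the high single digits at n = 21). These values were
fixed once from the group statistics the design targets.

Time-series mode (`generate_timeseries_study()`) convolves each trial's
pattern with the canonical double-gamma HRF (peaks at 6 s and 16 s,
undershoot ratio 1/6, 16 microtime bins per TR), adds a smooth
low-frequency global drift (sum of slow sinusoids, per-voxel gain
1 ± 0.1) expressed through a designated white-matter compartment, motion
random walks with voxelwise artifact couplings, and white noise of SD
`noise_sd`. What the generator does **not** emulate: physiological noise
and its spatial correlation structure, motion-induced geometric
distortion, slice-timing offsets, susceptibility artifacts,
inter-subject anatomical variability (all data share one grid), and any
semantic structure relating different videos. Passing tests therefore
demonstrate the correctness and calibration of the *statistics*, not that
real data meet their assumptions.

## Numerical choices and degenerate inputs

* Correlations are clipped at `±(1 - 1e-7)` before `atanh`; self-correlation
  of identical patterns maps to the clipped value, not infinity.
* Zero-variance patterns: correlation treated as 0 with a logged count.
* Zero-variance voxels in group t maps: flagged signed infinities.
* Constant score vectors: all-zero weights with a warning, statistic 0.
* Degenerate paired tests (zero-variance differences): flagged infinite t
  (or t = 0, p = 1 for exactly identical conditions).
* Rank-deficient design matrices are rejected naming the collinear
  columns; condition numbers above `1e8` warn.
* The searchlight sphere includes boundary ties (`distance <= radius`)
  and the centre itself.

## Problem sizes

The suite and the acceptance script run everything at desk scale, chosen
so that a full study simulates and analyzes in minutes on one core: small
grids (roughly 1,000–16,000 voxels), 1,000 sign-flip permutations, and
Monte-Carlo experiments of 25–200 replicate studies (200 for the type-I
calibration, 50 for effect recovery and the null specificity checks, 25
for the power checks, 100 for the generator-calibration property). The
statistics under test are invariant to grid size; the experiments'
operating characteristics (power at the injected effect sizes, binomial
CIs) are stated alongside each test.

## Known limitations

* OLS without AR modelling slightly miscalibrates per-trial t values in
  autocorrelated real data; the RSAs use the maps relationally, but
  absolute t magnitudes should not be interpreted.
* Sign-flip cluster inference replaces the random-field-theory correction
  used by classic SPM pipelines; cluster p values will differ in the tails
  even on identical maps.
* Native-space analysis followed by normalization of result maps is
  intentionally not reproduced: the synthetic pipeline lives on one
  common grid throughout.
* The inter-subject Enc/ImRet run-exclusion convention (reference
  subject's run structure) is a synthetic-data convenience.
* Free-recall scoring consumes already-marked detail lists or score
  tables; no automated transcript scoring is attempted.
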