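---
title: "Methods: DMN-based anomaly screening for mental sub-health"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DMN-based anomaly screening for mental sub-health}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`dmnscreen` implements a resting-state fMRI screening pipeline built on a
single premise: coherent activity of the default mode network (DMN) is a
marker of mental health, and a systematic drop in the pairwise correlations
among its regions is an early-warning signal of mental sub-health — an
intermediate state between health and diagnosable disorder. Because the kind
of clinical cohort such a method targets is rarely shareable, the package
pairs every analysis stage with a ground-truth synthetic generator so that
all claims are testable end to end.

This vignette records the modelling choices, the tunable parameters with
their defaults and units, the numerical conventions, and what passing tests
on synthetic data do and do not establish about real data.

## The synthetic study conditions

`cohort_spec()` fixes the generating conditions; its defaults are the study
conditions every experiment in the test suite uses:

* acquisition: TR = 2 s, 160 acquired volumes per subject of which the
  first 10 are discarded (150 analyzed), 24 x 24 x 24 grid of 2 x 2 x 2 mm
  voxels (`default_atlas()`), four disjoint 5 x 5 x 5-voxel regions
  standing in for the prefrontal (1), parietal (2), temporal (3) and
  occipital (4) contributions to the DMN;
* cohorts: 74 healthy controls (class +1), and a 79-subject screening pool
  containing 10 planted sub-healthy subjects (class -1), mirroring the
  sample sizes such a screening study works at;
* connectivity: every region pair has expected correlation `cc_healthy =
  0.6` in healthy subjects and `cc_subhealthy = 0.25` in sub-healthy ones.
  The published account of this contrast is a boxplot, not a table, so
  these two values are the one place the generator is calibrated by
  judgement: 0.6 is a typical within-DMN resting-state correlation after
  band-pass filtering, and 0.25 produces clearly lowered but still positive
  correlations. They are configurable and all six pairs share one value per
  class (per-pair spread in real data carries no published numbers to
  match);
* noise: unit-variance region signals plus i.i.d. voxel noise with
  `noise_sd = 1`; background voxels are pure noise.

Region signals are built from a shared latent source: region *r* receives
`sqrt(rho) * common + sqrt(1 - rho) * independent_r`, each term a Gaussian
series ideal-filtered to 0.01–0.08 Hz and standardized. Band-limited latent
signals (rather than sinusoids) matter because the same volumes feed three
spectrally sensitive biomarkers: the signal must survive the analysis
band-pass, occupy many frequency bins, and carry realistic rank structure
for the concordance statistic.

Motion traces default to sub-threshold jitter (translation sd 0.2 mm,
rotation sd 0.15 deg); `motion_spike_prob` plants a supra-threshold spike in
a configurable fraction of subjects to exercise the exclusion rule, and is 0
by default so cohort sizes stay exact.

What the generator deliberately omits: scanner artifacts, slice-timing and
realignment residuals, anatomical realism of DMN geometry, physiological
confounds, and between-subject variability in the target correlation.
Passing tests therefore establish internal correctness of the statistics
and the recoverability of planted effects at realistic effect sizes — not
robustness to the full messiness of clinical fMRI.

## Preprocessing variants

Each voxelwise metric uses its own variant (`preproc_plan()`):

| metric | steps |
|--------|----------------------------------|
| FC     | smooth (5 mm FWHM), detrend, band-pass 0.01–0.08 Hz |
| ReHo   | detrend, band-pass 0.01–0.08 Hz (no smoothing) |
| fALFF  | smooth (5 mm FWHM), detrend (no band-pass) |

ReHo skips smoothing because smoothing manufactures rank agreement among
neighbours; fALFF skips the band-pass because the statistic is precisely a
ratio of band amplitude to full-spectrum amplitude.

Numerical conventions:

* the temporal filter is an ideal (frequency-domain boxcar) filter with
  inclusive band edges, matching the convention of the standard
  resting-state toolchains and making on-bin pass/stop behaviour exact;
  the DC bin is outside the band, so filtered series are mean-free;
* smoothing is separable Gaussian convolution with
  `sigma = FWHM / (2 sqrt(2 ln 2))` per axis scaled by voxel size, with
  symmetric (reflective) boundary padding so per-volume mass is preserved;
* nuisance regression and detrending are exact least-squares residuals
  (QR), with linearly dependent confound columns dropped under a warning;
* the motion rule excludes a subject when any translation exceeds 2 mm or
  any rotation parameter exceeds 2 degrees, strictly; each rotation
  parameter is compared directly, with no composite norm;
* the order nuisance regression -> detrend -> filter is fixed; the steps
  are all linear, and the pipelines used here either include no confounds
  (synthetic default) or are insensitive to the detrend/regression order
  because the design always contains the intercept and trend terms.

### Fast equivalent paths

Smoothing, detrending and filtering are linear, and region averaging
commutes with the temporal steps. Two algebraically exact shortcuts exploit
this: region-mean series of smoothed data are computed as
smoothed-indicator-weighted sums of the raw data (`cohort_features(method =
"projected")`), and voxelwise maps restricted to the small DMN mask use a
sparse row block of the smoothing operator (`cohort_biomarker_maps()`).
Both agree with the materialized voxelwise route to ~1e-10 (tested), and
make the cohort-scale experiments run in minutes on one CPU.

## Template construction

The structural-functional template is the voxelwise product of a 4-label
structural atlas with a binarized functional DMN mask:

1. per healthy subject, spatial ICA (`fastica_decompose()`, fixed-point
   logcosh contrast, symmetric decorrelation, PCA whitening to
   `n_components = 20`) on FC-plan data; the model order is a configured
   constant — automatic order selection is out of scope;
2. a subject DMN map is assembled from the components matching a binary
   reference mask (the atlas support); see below;
3. maps are averaged, z-scored, thresholded at z >= 2.0 (inclusive), and
   the surviving mask multiplies the atlas labels. Losing any of the four
   labels in the product is an error, because feature extraction needs all
   four ROIs.

Component matching scores each component by the Pearson correlation of its
absolute map with the reference, breaking ties towards the larger in-mask
mean, and fixes signs so in-mask means are positive. The default
(`combine = "sum"`) sums all components scoring at least 80% of the best
match. The single-best alternative (`combine = "best"`) is available, but
on data whose network regions are spatially disjoint — exactly what the
generator produces — spatial ICA splits the network into near-equally
matching single-region components, and winner-take-all selection then
leaves regions uncovered in the group mean at realistic cohort sizes. When
one component dominates the match, which is the typical situation on real
data, the two settings coincide.

ICA numerical choices: convergence is declared when the symmetric
decorrelation change falls below 1e-3 (up to 500 iterations). Band-passed
series retain only ~22 of 150 frequency bins, so the whitened noise
components are nearly rotation-degenerate and a tighter tolerance stalls on
legitimate inputs; non-convergent runs are retried with derived seeds (5
attempts) before erroring. Everything is deterministic given the seed.

z-scoring of maps uses the whole grid as support on synthetic data (every
voxel carries signal or noise); on real data a brain mask would be supplied.

## Features and the two-fold classifier

A subject's feature vector is the six pairwise Pearson correlations among
the four region-mean series, in the fixed order 1–2, 1–3, 2–3, 1–4, 2–4,
3–4 (prefrontal, parietal, temporal, occipital). The order is part of the
on-disk TSV format and is deliberately not lexicographic. Raw correlations
are used — no Fisher transform — because the classifier consumes them
directly.

The two-fold SVM (`tfsvm_fit()`) addresses screening without labelled
negatives:

1. **One-class bootstrap.** An RBF one-class SVM is trained on 50 randomly
   chosen healthy controls (features unscaled). Hyperparameters (nu, gamma)
   are grid-searched with 7-fold cross-validation on the positives,
   maximizing mean held-out acceptance. Acceptance plateaus over much of
   the grid, so values within one training sample (1/n) of the maximum are
   treated as ties, resolved towards the smallest nu and then the smallest
   gamma — the least-rejecting, smoothest boundary. Without the plateau
   rule, fold noise occasionally selects degenerate corners (tiny gamma)
   whose refit boundary rejects a quarter of held-out data. Defaults:
   nu in {0.01, 0.05, 0.1, 0.2}, gamma in 2^(-15..3) (log-spaced, step 2^2).
   The decision convention maps non-negative decision values to +1.
2. **Two-class refinement.** Pool subjects predicted -1 seed a negative
   set. Iteratively, a soft-margin RBF SVM is trained on the 50 positives
   plus all accumulated negatives, with (cost, gamma) grid-searched by
   stratified 5-fold CV accuracy (cost in 2^(-5..15), gamma in 2^(-15..3));
   remaining pool subjects predicted -1 join the set. Negatives never
   revert (a `allow_relabel` flag exists for sensitivity analysis), so the
   loop terminates in at most pool-size rounds, stopping at the first round
   that adds nothing. A pool with zero initial negatives is a valid outcome
   with no second stage.
3. **Metrics.** The held-out test set is all-positive, so accuracy is the
   percentage labelled +1, the false-positive rate is its complement, and
   the true-positive rate equals the accuracy (`evaluate_screening()`).

No class reweighting is applied in the refinement stage despite the 50 vs
~10 imbalance; the imbalance is part of the design being reproduced and the
configuration is exposed.

A note on attainable one-class acceptance: for a 6-dimensional Gaussian
feature cloud of 50 training points, the best held-out acceptance any
(nu, gamma) on the default grid achieves is about 87% (measured by direct
Monte-Carlo over the grid); the one-class hull of so few points in six
dimensions necessarily rejects over a tenth of fresh draws. The meaningful
performance claim is therefore comparative — the refined classifier's
held-out acceptance is at least the initial one's — and that is what the
acceptance suite asserts across seeds, alongside full recovery of the
planted sub-healthy subjects.

## Voxelwise biomarkers

All biomarkers are computed on the DMN mask (template support) only.

* **Seed FC** (`seed_fc_map()`): Pearson correlation of each mask voxel
  with the seed region's mean series; the prefrontal and parietal cortices
  are the conventional seeds. Two normalizations are provided because "z-
  scored FC maps" is ambiguous: `transform = "spatial"` (default)
  standardizes the r map over the mask; `transform = "fisher"` applies
  voxelwise atanh(r) with no spatial standardization. The group-difference
  experiments on synthetic cohorts use the Fisher option: the generator's
  uniform connectivity drop yields near-two-level r maps, and spatial
  standardization of a two-level map depends only on the level proportions
  — it cancels exactly the group contrast being tested. Real data, with
  continuous spatial variation, do not degenerate this way, which is why
  both options are kept.
* **ReHo** (`reho_map()`, `kcc()`): Kendall's coefficient of concordance
  W of each voxel's time series with its 26 face/edge/corner neighbours,
  computed on unsmoothed data. Ranks use mid-rank (average) tie handling
  with no tie-correction term. Neighbourhoods are clipped to in-mask,
  in-bounds voxels and the actual member count K enters the formula;
  isolated voxels (K = 1) get NA.
* **fALFF** (`falff_map()`): the sum of spectral amplitudes (square roots
  of power) over 0.01–0.08 Hz divided by the sum over the full range up to
  Nyquist (0.25 Hz at TR = 2 s), computed on unfiltered (smoothed,
  detrended) data. The DC bin is excluded from the denominator since
  detrended data carry no DC fluctuation; zero-amplitude voxels get ratio 0
  under a message.

ReHo and fALFF maps are z-scored over the mask (mask-wide, not whole-brain,
statistics). A constant map over the mask makes z-scoring undefined and is
an error by contract.

## Group statistics

`two_sample_t()` computes the voxelwise pooled-variance two-sample t
statistic with unbiased variances, sub-healthy group first (decreases are
negative). Voxels with zero pooled variance get T = 0 under a message. A
Welch denominator sits behind `welch = TRUE` for sensitivity analysis only.

`cluster_threshold()` implements the fixed operating point |T| > 2.1
(strict) with a minimum cluster volume of 784 mm^3 — 98 voxels at 2 mm
isotropic. The threshold pair is the published operating point of a
Monte-Carlo cluster correction; the correction itself is out of scope and
its output is hard-coded as the default. Positive and negative voxels are
clustered separately under 26-connectivity (the convention of the standard
AlphaSim/REST tooling; 18 and 6 are selectable), components are ranked by
size, and peaks are reported in grid and grid-centred mm coordinates.
Clusters are annotated with their overlap fractions against the four
template regions, replacing anatomical-atlas lookup, which is out of scope.

## Problem sizes used by the validation suite

The acceptance experiments run at the full default study conditions: 20
replicate seeds for classifier recovery (74 + 79 subjects each), 10 seeds
for the group-difference direction (74 subjects each, with the null
comparison formed by relabelling healthy subjects from the same cohorts),
and a 12-subject cohort for template recovery. These sizes were chosen so
the whole suite completes in well under half an hour on a single desktop
core while keeping every Monte-Carlo margin wide.

## Known limitations

* The generator plants a single global connectivity level per class; it
  cannot probe graded or pair-specific deficits, nor inter-subject
  heterogeneity of the healthy correlation.
* Spatial ICA on exactly-disjoint region supports is a harder separation
  problem than real DMN extraction in one respect (component splitting,
  handled by `combine = "sum"`) and an easier one in others (no artifact
  components competing for the match).
* The spatial-z FC normalization is degenerate under the generator (see
  above); conclusions about which normalization is preferable on real data
  cannot be drawn from these experiments.
* Cluster inference uses the fixed printed operating point; no
  data-adaptive correction is performed.
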