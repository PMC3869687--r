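---
title: "Voxel-based morphometry from CT and MR head volumes: methods and design"
author: "ctvbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-based morphometry from CT and MR head volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`ctvbm` implements a complete voxel-based morphometry (VBM) chain that
accepts X-ray CT head volumes as well as T1-weighted MR: brain extraction
(CT only), prior-weighted Gaussian-mixture tissue segmentation, spatial
normalization of the gray-matter map to a gray-matter template, isotropic
Gaussian smoothing, and a mass-univariate two-group general linear model
with cluster-extent thresholding and cluster-level false-discovery-rate
(FDR) control. A synthetic head-phantom generator provides paired CT/MR
cohorts with known tissue labels and injectable regional atrophy, and is
the substrate for every statistical claim the test suite makes.

This vignette records the model assumptions, the tunable parameters and
their defaults, what the phantom does and does not emulate, the numerical
choices, and the known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

# Pipeline model

## CT brain extraction

CT intensities are calibrated Hounsfield units (HU): air -1000, water 0,
brain parenchyma roughly 0-60, bone several hundred and above. Brain
extraction exploits this: soft-tissue candidates are voxels with
`loHu < HU <= hiHu` (default 0-100), reduced to their largest 6-connected
component, morphologically closed with an ellipsoidal element
(`closeRadiusMm`, default 4 mm), hole-filled so interior CSF is retained,
and reduced to a single component again. Voxels outside the mask are set to
`loHu`, so the output feeds the segmenter directly. Taking the largest
component *before* closing and hole-filling is deliberate: filling first
would flood the skull shell (which is enclosed between candidate scalp and
candidate brain) and merge scalp, skull and brain into one component. The
lower bound is strict so that the operation is idempotent on its own
output. MR volumes are not skull-stripped; they enter segmentation whole.

## Tissue segmentation

Segmentation is a prior-weighted Gaussian mixture fitted by
expectation-maximization (EM). Each tissue class c (gray matter, white
matter, CSF, other) owns one or more Gaussians g; the joint density of
intensity y at voxel v is

    p(y_v) = sum_c prior_c(v) sum_{g in c} w_g N(y_v; mu_g, sigma_g^2)

with spatial priors `prior_c(v)` from a tissue-probability atlas
(the "other" prior is the complement) and within-class mixing weights
summing to one. The E-step responsibilities and the closed-form M-step are
standard; the log-likelihood is asserted non-decreasing. Key settings:

* `nGauss` — Gaussians per class. The MR regime uses 2/2/2/4
  (gm/wm/csf/other); the CT regime uses 2/2 for gray and white matter and a
  joint CSF+other total of 6-8, because CT packs air, bone remnants,
  partial-volume mixtures and CSF into a wide, multi-modal intensity range.
  `autoAdjustGaussians()` grids over the CT range per subject and keeps the
  most successful fit (converged, gray-matter posterior Dice >= 0.6 against
  the prior MAP labeling; ties broken by mean log-likelihood, then fewer
  Gaussians). The success score guards against the CT failure mode of gray
  matter leaking into bone or CSF.
* `samplingMm` — EM runs on a sub-grid at this spacing (3 mm MR, 2 mm CT
  presets); class posteriors are evaluated at full resolution on exit.
* `biasReg` — MR only: a multiplicative bias field on a coarse (4^3)
  separable cosine basis is re-estimated every fourth iteration from the
  log-residuals with quadratic penalty `biasReg`; `Inf` disables it. CT
  intensities are calibrated, so the CT regime runs with the bias field
  off (the "heavy regularization" reading of the CT parameterization).
* Initialization is from the prior MAP labeling with intensity-quantile
  splits for multi-Gaussian classes; when the priors are spatially flat
  (no MAP information) all Gaussians take staggered global quantiles, a
  deterministic symmetric-start breaker.
* The M-step applies a variance floor of 1e-6 times the data variance.
  This is the constrained maximizer (EM stays monotone) and it blocks the
  spike degeneracy of unpenalized mixtures; it is not optional because
  brain-extracted CT contains an exact intensity point mass (the windowed
  background), which otherwise collapses a component deterministically.
  Jittered restarts remain for genuine numerical breakdown.

## Spatial normalization

Normalization is pull-back: template-space world coordinate x maps to
source-space world coordinate `A (x + u(x))`, with `A` a 12-parameter
affine and `u` a separable low-frequency cosine displacement field over the
template field of view. The affine minimizes the variance-normalized mean
squared intensity difference after optimal global intensity scaling,
starting from center-of-mass plus second-moment initialization, with a
quadratic penalty on rotation/zoom/shear departures from that
initialization (`affineReg`, default 5). The penalty matters: gray-matter
maps give the similarity surface long flat valleys in the zoom/shear
directions, and without it per-subject noise picks an arbitrary point of
the valley, which inflates between-subject variance at the cortical shell.

The warp minimizes the same data term plus `regLambda` times the membrane
energy of `u` over the cosine coefficients, by Gauss-Newton with step
halving (the objective trace is non-increasing by construction) and a
displacement cap of a quarter field of view. The basis size per axis is
`max(2, floor(FOV/cutoffMm))`; the frequency cutoff is read as the shortest
represented spatial wavelength in mm (35 for CT, 25 for MR), treating the
"Hz" unit sometimes attached to such cutoffs as a misprint, since a
temporal frequency is dimensionally impossible for a spatial basis. A
small ridge on the zero-frequency modes keeps global translation in the
affine and guarantees that `regLambda -> Inf` drives the warp to zero.
Both estimations run on 8-mm-smoothed copies of the maps (`estFwhmMm`),
the standard trick to stop the optimizer chasing segmentation speckle; the
estimated parameters are applied to the unsmoothed gray-matter map. No
Jacobian modulation is applied: the analyzed quantity is smoothed,
unmodulated gray-matter density, under the reading that regional intensity
is then equivalent to regional gray-matter volume.

## Smoothing and statistics

Smoothing is separable Gaussian convolution with
`sigma = FWHM / (2 sqrt(2 ln 2))` per axis (default FWHM 12 mm), truncated
at 4 sigma, zero-padded (gray matter is zero outside the head, so zeros
are the physically consistent boundary).

Global normalization is proportional scaling: each image is rescaled so
its global gray-matter signal (mean of voxels above one eighth of the
volume mean) equals the cohort mean of the globals. The GLM is then the
two-group cell-means model per masked voxel (mask: mean gray-matter
density across subjects > 0.05), with the one-tailed contrast
controls > patients and `df = n - 2`; proportional scaling, not a
covariate, absorbs the global signal, so no degree of freedom is spent on
it (this is what makes the df-10 t/Z/P triples of a 5-vs-7 design
internally consistent). t maps convert to unit-normal Z through
complementary log-tail distribution functions, which survive |t| up to ~40
without saturating.

Cluster inference: suprathreshold voxels (upper-tail p < `voxelP`, default
0.005) are labeled at connectivity 18 (the face+edge convention), clusters
below `extentK` voxels are discarded (defaults 123 for CT, 381 for MR — at
2 mm voxels 984 and 3048 mm^3), and each surviving cluster gets an
uncorrected cluster p-value from either

* the Gaussian-random-field expected-cluster-extent approximation
  (`clusterPRFT`): with Z threshold u, expected cluster count from the 3D
  Euler-characteristic density over the mask's resel count (resels from
  the residual-smoothness FWHM estimated off standardized residual spatial
  derivatives), expected cluster size from the suprathreshold volume, and
  `P(extent >= k) = exp(-beta k^(2/3))`; or
* a relabeling permutation null of the maximum cluster size
  (`clusterPPerm`), `p = (1 + #{perm max >= k}) / (nPerm + 1)`.

Benjamini-Hochberg step-up over the cluster p-values at `clusterQ`
(default 0.05) yields the significance flags — FDR across clusters, not
voxels. The cluster table reports, per local peak (at most 3 per cluster,
at least 8 mm apart): cluster size in voxels and mm^3, peak uncorrected P,
peak t, peak Z, and the peak world coordinate in template-space mm.

# The head phantom

The generator emulates a two-group cross-sectional cohort, not scanner
physics. The canonical head is a set of nested ellipsoidal shells (white
matter core; gray-matter shell whose inner boundary is sinusoidally
perturbed as a stand-in for gyrification; subarachnoid CSF; skull; scalp)
plus central ventricles and an optional detached head-holder slab. Default
rendering means: CT (HU) air -1000, skin 40, skull 1000, holder 60, CSF 8,
gray 35, white 27 — a realistically small 8-HU gray/white contrast, which
is precisely what makes CT segmentation harder than MR; T1-MR CSF 10,
gray 60, white 90, skull 20, skin 50 times a smooth multiplicative bias
field (`exp(0.2 s)` with a fixed 1.25 dynamic range for `s`) — the
WM > GM > CSF ordering of T1. Noise is white Gaussian (5 HU / 5 units).

Each subject is an independently jittered copy of the canonical phantom:
log-scale sd 0.02 per axis, rotation sd 2 degrees, translation sd 2 mm,
plus a smooth random warp of 2 mm RMS amplitude on a 3^3 cosine basis.
Patients receive the atrophy lesion before jittering: inside a sphere
(default radius 10 mm, centered mid-thickness of the shell), each GM voxel
independently becomes CSF with probability `severity`. Rendering is
anti-aliased: the subject transform is applied to the tissue indicators
with trilinear weighting, so a rendered voxel carries the tissue mixture
it covers, as a real scanner voxel does. This matters at the 48^3 / 4 mm
scale used throughout the tests: nearest-neighbour re-discretization of
the thin cortical shell otherwise contributes more between-subject
variance at shell points than the lesion effect itself.

The tissue-prior atlas is built as a population average (tissue indicators
averaged over six independent gyral-phase draws, then smoothed 6 mm), the
way real tissue probability maps are population averages; the smoothed GM
prior doubles as the normalization template. Per-subject truth labels are
the majority tissue per voxel.

What the phantom does **not** emulate: realistic cortical folding, beam
hardening and CT artifacts, k-space artifacts, anatomy outside the listed
shells, and any within-group anatomical heterogeneity beyond the jitter
model (all subjects of a cohort share one canonical geometry). Passing
tests therefore demonstrate the correctness and calibration of the
pipeline machinery on data whose generative truth is known — not clinical
performance on real heads.

# Problem sizes used by the test suite

Phantom simulations run at 48^3 voxels of 4 mm (192 mm field of view),
with the analysis grid at 4 mm and the extent thresholds volume-matched
accordingly (984 mm^3 -> 15 voxels, 3048 mm^3 -> 48 voxels). Registration
objectives are sampled on 8-16 mm sub-grids and EM on 8-12 mm sub-grids in
the batch profiles. The null-calibration suite runs 200 seeded null
cohorts through a lean profile (affine-only normalization, extent
threshold 0, 199 permutations): cluster-level permutation inference is
calibrated under group exchangeability whatever the preprocessing
settings, so the cheapest faithful chain is the right one to calibrate,
and an extent veto would mask miscalibration rather than reveal it. The
lesion-recovery suite runs 12 CT and 6 MR cohorts at the modality-default
profile (the MR chain costs roughly three times the CT chain per cohort).
`scripts/acceptance.R` re-runs scaled versions of both (60 null cohorts,
12 CT and 6 MR effect cohorts).

# Known limitations

* **Prior alignment is load-bearing for CT.** Without the per-subject
  affine alignment of the priors (`priorAlign`), residual rotation/zoom
  jitter misplaces the priors by about a voxel at the cortical shell and
  the 8-HU CT contrast cannot compensate: phantom gray-matter Dice falls
  from ~0.86 to ~0.72 and lesion detection collapses. With it, the CT arm
  detects the default 10-mm, 30%-severity lesion in well over 80% of
  cohorts (measured in the acceptance suite).
* **The MR arm absorbs sub-voxel speckled atrophy at reduced resolution.**
  The lesion mechanism converts scattered single GM voxels to CSF; under
  the anti-aliased rendering these become GM/CSF partial volumes at
  intermediate T1 intensity (~45 of GM 60 / CSF 10), which the MR regime's
  two-Gaussian gray-matter class claims as gray matter, erasing most of
  the effect (lesion contrast ~0.04 vs ~0.13 in CT). At real MR
  resolution (~1.25 mm) such voxels would be resolved as pure CSF; the
  generator's `renderVoxelMm` option emulates this by rendering finer than
  the label grid, which recovers part of the signal at substantial cost.
  At the 48^3 test scale the MR detection rate stays far below the CT
  arm's, and the corresponding acceptance assertion is expected to fail —
  a measured property of this phantom regime, reported as such.
* **Cluster-extent power for compact lesions is intrinsically marginal
  here.** The lesion spans ~65 analysis voxels (4189 mm^3); with 12-mm
  smoothing on smooth phantom anatomy the realized residual smoothness is
  15-22 mm FWHM, at which the expected null cluster is tens of voxels, so
  detections hinge on the segmentation preserving the full lesion
  contrast. The permutation max-cluster-size statistic additionally
  saturates under strong effects (near-true relabelings recover nearly
  the same cluster), which is why effect recovery is assessed in the
  random-field mode while calibration is assessed in permutation mode.
  Strengthening the warp reduces residual smoothness but removes lesion
  signal in proportion, because the phantom's smooth shell leaves the
  warp locally unconstrained ("lesion chasing") — a milder version of the
  same trade-off exists in real VBM.
* The RFT cluster p uses the Gaussian-field approximation on the Z map;
  at df = 10 this is optimistic in the extreme tail, which is why the
  permutation mode exists and is used for calibration claims.
* The affine/warp estimators are local optimizers with moment-based
  initialization; they assume the head is roughly placed (center-of-mass
  alignment) and will not recover gross misorientations.
* The bias-field model is a coarse multiplicative cosine expansion fitted
  to log-residuals; it is adequate for the phantom's smooth field, not a
  general-purpose inhomogeneity correction.
* `cutoffMm` interacts with the basis rule `max(2, floor(FOV/cutoff))`;
  for small fields of view the warp is deliberately stiff.

# Reproducibility

Every stochastic step takes an explicit seed (`fitMixture` restarts,
phantom generation, permutation draws), and `runVBM` caches per-subject
stage outputs keyed on a configuration fingerprint, so re-running a study
directory with an unchanged configuration reproduces the cluster table
byte for byte.
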