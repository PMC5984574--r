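---
title: "Pseudo-healthy synthesis for unsupervised lesion segmentation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-healthy synthesis for unsupervised lesion segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the modelling idea

White-matter hyperintensities (WMH) of presumed vascular origin appear bright
on FLAIR MRI and are a core radiological marker of cerebral small vessel
disease. Manual delineation is slow and variable; supervised segmentation
needs labelled cohorts that transfer poorly across scanners. `lesionsynth`
implements a fully unsupervised alternative: treat segmentation as **outlier
detection against voxel-wise models of healthy anatomy**, learned from a
training set of (near-)healthy subjects in a common space.

Two per-voxel abnormality maps are computed for a test subject:

* **`L^SYN` — the pseudo-healthy synthesis residual.** At every voxel a
  Nadaraya–Watson kernel regression, fitted on healthy co-registered
  T1-w/FLAIR pairs, maps the subject's T1 intensity to the FLAIR intensity a
  healthy brain would show there. Subtracting the synthesised FLAIR from the
  true FLAIR leaves pathology: lesions are bright on FLAIR but, at the same
  voxel, the T1 intensity still resembles healthy tissue (or GM-like
  hypointensity), so the regression predicts healthy WM and the residual is
  large. In uniform WM the regression sees a single intensity cluster and
  *extrapolates a constant* — exactly the behaviour that makes the synthesis
  robust to T1-visible lesions.
* **`L^FLAIR` — the mixture abnormality map.** A two-component 1-D Gaussian
  mixture of healthy FLAIR intensity is fitted per voxel (one effective
  component inside a tissue, two at tissue boundaries). At test time the map
  is a shifted negative log-density of the observed intensity, floored at
  zero, and **hard-zeroed below 1000** — the normalised WM/GM midpoint — so
  only hyperintensities are flagged.

The maps are fused per voxel with a spatial lesion-frequency atlas by two
**one-class SVMs** (one for WM-routed voxels, one for GM), trained on the
same healthy cohort; outlier scores form `L^SVM`. A **dense conditional
random field** over the FLAIR volume binarises the scores, removing isolated
false positives while preserving coherent lesions.

# Stage-by-stage detail

## Intensity normalisation

All voxel-wise modelling compares intensities across subjects, so intensities
must live on one scale — and the mapping must not depend on lesion load.
Quantile scaling, histogram matching and z-scoring all shift with the volume
of hyperintensity. Instead, a **fixed point** is computed from tissue that is
almost surely healthy: voxels with > 0.95 WM (resp. GM) probability, further
trimmed to the central 95% of the intensity sample. The mean of the refined
WM mean and refined GM mean is scaled linearly to 1000. The "95% interval"
is implemented as the empirical 2.5–97.5 percentile band (distribution-free;
a mean ± 1.96 SD variant is available via `interval = "sd"`). T1 and FLAIR
are normalised independently. On phantoms, adding lesions occupying up to
10% of the WM changes the FLAIR scale factor by well under 1%: lesion voxels
drop out through the probability filter (real tissue segmentations are
unreliable inside lesions — the phantom generator mirrors this) or through
the percentile trim.

## Synthesis bank

For each voxel, `(t, f)` pairs are pooled from an `a^3 = 5^3` patch around
the voxel in every training pair (patches are clipped at volume edges rather
than padded — padding would fabricate intensities), T1 capped at
`t_max = 1500`. The Nadaraya–Watson estimate with Gaussian kernel is
evaluated at `m = 100` points `k_j = t_max j / m`; synthesis is then a table
lookup at index `ceiling(m t / t_max)`, clamped to `[1, m]`.

The bandwidth `h` is not dictated by the method; the package default is
`h = 50` normalised units (about 1/30 of `t_max`): wide enough to smooth
scanner noise, narrow enough that the GM peak of a mixed-tissue curve
survives. Where the kernel denominator underflows (evaluation far from every
training `t`), the response of the nearest training point is used — this is
the extrapolation contract that yields constant curves in uniform tissue.

Two corrections follow:

* **Transfer function.** Kernel smoothing compresses contrast toward the
  mean, so the extreme FLAIR intensities are never synthesised. Per training
  subject, the monotone quantile map from the synthetic to the true FLAIR
  intensity distribution is computed over brain (nonzero) voxels, sampled at
  256 knots over [0, 2000]; the pointwise **median across subjects** is
  applied to every synthesis. Brain-masked histograms are used: background
  zeros would otherwise dominate both distributions.
* **Periventricular cap.** Healthy ageing brains show benign FLAIR
  brightening along the ventricular walls ("bands and caps"). Trained on
  such subjects, the synthesis would reproduce that brightening and mask
  genuine periventricular WMH — the predominant WMH location. Therefore WM
  voxels within 15 mm of the ventricles (Euclidean distance transform of the
  training ventricle mask) are capped at the expected healthy-WM intensity.
  The cap value is the scalar mean of training FLAIR over all WM voxels in
  the 15 mm shell: a voxel-wise cross-subject mean would simply reproduce
  the bands it is meant to suppress, so the shell-wide mean — in which the
  thin band rim is a small minority — is the faithful reading of "expected
  healthy WM intensity in this region".

## FLAIR mixture bank

Per voxel, nonzero FLAIR intensities are pooled from a `b^3 = 5^3` patch
across subjects and a two-component mixture fitted by EM: deterministic
initialisation (split at the sample median, equal weights, common SD),
convergence when the per-sample mean log-likelihood moves by less than
`1e-6` (the scale-free reading of a log-likelihood tolerance; it keeps the
stopping rule independent of how many samples a patch pools), at most 200
iterations, component SDs floored at 1 normalised unit to prevent collapse. The observed-data
log-likelihood is non-decreasing across iterations and is returned as a
trace. On genuinely unimodal voxels the two components overlap heavily and
the likelihood ridge is nearly flat; such voxels may exhaust the iteration
cap with a negligible likelihood gradient, which the per-voxel diagnostics
record. Voxels with fewer than 8 pooled samples fall back to a single
Gaussian duplicated into both components.

The printed form of the test-time quantity is a mixture *density* while its
described behaviour is "large for abnormal"; the package therefore computes
`-log(density + 1e-300)`, anchored by subtracting its minimum over the brain
(so healthy tissue sits near 0 and feature scales are comparable across
subjects) and floored at 0, with the raw-density variant available as
`variant = "density"`. Both variants keep the exact hard zero below 1000.

## One-class fusion

Each brain voxel contributes the 3-vector `[L^SYN, L^FLAIR, atlas]` and is
routed to WM or GM by the larger tissue probability; voxels with
`wm + gm < 0.5` (CSF, background) are excluded — no classifier is trained
for them and their score is defined as 0. Per route, 50 000 vectors are
sampled uniformly (seeded), scaled per dimension by sample median/IQR
(distance-based kernels need commensurate scales; the method itself does not
prescribe a scaling), and a one-class RBF SVM is trained with outlier
fraction ν = 0.05 (WM) and ν = 0.003 (GM). The RBF width defaults to the
reciprocal of (dimension × mean per-dimension variance of the scaled
sample). When reference lesion masks exist for training subjects they are
dilated by one voxel and excluded from the pools.

Two numerical notes. First, the quadratic-programme termination tolerance is
set to `1e-5` (libsvm's default `1e-3` leaves free support vectors with
slightly negative decision values, visibly inflating the measured training
outlier fraction at ν = 0.003). Second, with the default kernel width the
one-class decision surface can be nearly flat — numerically zero — at the
centre of an isotropic training cloud; scores there are at noise scale
rather than exactly zero, which is why inlier behaviour is asserted with a
tolerance in the tests. Outlier scores are `max(0, -decision value)`:
inliers score exactly 0, outliers their distance beyond the boundary.

## CRF refinement

`L^SVM` feeds a fully connected two-label Potts CRF over the volume with two
Gaussian pairwise kernels — smoothness (`w1`, spatial SD `sigma_alpha`) and
appearance (`w2`, spatial SD `sigma_beta`, intensity SD `sigma_gamma`) —
inferred by parallel mean-field updates. Choices:

* **Unary bridge.** The method does not state how scores become
  probabilities; the package uses `p = 1 - exp(-s / tau)` clipped to
  `[1e-6, 1 - 1e-6]`, with `tau` set during training to the 90th percentile
  of positive training scores (scores comparable to what the healthy cohort
  itself produces should not be confidently lesion). Scores below `1e-3`
  are excluded from that calibration: they are decision-value noise from
  the QP termination tolerance on the numerically flat part of the
  one-class surface, and letting them into the percentile collapses the
  temperature.
* **Kernel normalisation.** Both kernels are truncated at 3σ and divided by
  their full-window spatial sums, so `w1` and `w2` bound the total pairwise
  influence on a voxel (the convention of dense-CRF filtering
  implementations). Without this, the ~400-fold kernel mass of a 3 mm
  Gaussian window drowns any unary.
* **Parameters.** `w2 = 8` and `sigma_gamma = 2.5` are the two tuned values;
  `w1 = 1`, `sigma_alpha = sigma_beta = 3` mm, 5 iterations are declared
  package defaults. `sigma_gamma` is expressed on a 0–255 intensity scale,
  so the intensity volume is linearly mapped to [0, 255] before the
  appearance term.
* **Tractability.** Message sums run over the truncated window; update
  candidates are restricted to voxels whose initial lesion belief exceeds
  `1e-3`, dilated by the window radius (every other voxel keeps a unary
  marginal the pairwise terms could not move; messages still sum over all
  window voxels). On grids of up to 27 voxels the identical model admits an
  exhaustive minimum-energy labelling via Gray-code enumeration, which the
  test-suite uses as the mean-field oracle; `exact_map_small()` exposes it
  with a 4096-labelling cap.

## Evaluation battery

Dice, precision and recall with explicit empty-mask conventions (both empty:
1; exactly one empty: Dice 0, undefined ratios `NA`); average symmetric
surface distance and Hausdorff distance between 6-connected boundary voxels
(Euclidean, mm; undefined for empty masks); ICC(A,1) from the two-rater
ANOVA decomposition; Bland–Altman statistics on ICV-normalised volumes with
ratio differences `d = (a - t) / (0.5 (a + t))`, RPC `1.96 SD(d)`, CV, and a
two-sided Wilcoxon signed-rank test of zero mean difference (lesion volumes
are non-normal, so a non-parametric location test); Spearman correlation
(average ranks) with combined 0–6 clinical WMH ratings; and Dice binned by
lesion volume (components at 26-connectivity, Dice inside each component's
bounding box; <0.01 / 0.01–0.1 / 0.1–1 / 1–10 / ≥10 ml) or by subject volume
(<5 / 5–10 / 10–15 / >15 ml). All of these are cross-checked against
brute-force oracles in the test-suite.

# The phantom generator

The study conditions are emulated by `generate_cohort()`: concentric shells
(CSF "ventricle" core, WM shell, GM rim) on a default 48³ lattice at 1 mm —
the method is voxel-wise in a common space, so any reproducible layout
containing the three tissue classes exercises every stage, without any
template download. Per class, T1 is bright-WM/darker-GM/dark-CSF and FLAIR
is suppressed-CSF/bright-GM/intermediate-WM, with per-class texture SDs,
additive scanner noise (SD 0.02 raw units against a WM/GM contrast of 0.15–
0.2), and partial-volume smoothing (σ 0.5 mm) of the noise-free tissue
image. Spherical lesions (radius 2–4 mm, three per subject by default) are
placed inside the WM shell, hard-edged and then smoothed like tissue, adding
+0.25 raw units on FLAIR and −0.15 on T1 — hyperintense where detection
happens, hypointense where synthesis must extrapolate. Healthy subjects
instead receive a +0.12 brightening of the 2-voxel periventricular WM rim
(the benign bands/caps the capping stage must neutralise). Lesion voxels
keep a *reduced* WM probability (0.6), because real anatomical pipelines do
not segment lesions as clean WM — this is also what makes the normalisation
fixed point lesion-load invariant. The atlas for all-healthy cohorts is the
analytic prior `exp(-d / 5 mm)` of ventricle distance (zero inside the
ventricles), mimicking the periventricular predominance of WMH; lesioned
cohorts average their reference masks.

What the phantom does **not** emulate — and what passing tests therefore do
not show about clinical data: cortical folding and anatomical variability
(there is no registration error, the phantoms are co-registered by
construction), MR physics (bias fields, ringing, eddy-current distortion,
slice-thickness partial volumes), multi-protocol contrast variation, and
non-WMH pathologies. The interfaces accept any co-registered NIfTI bundles,
so real (externally preprocessed) data can be substituted wherever available.

# Reproducibility and problem sizes

A single master seed is fanned out deterministically (Lehmer-style mixing,
always below 2³¹) to subject generation, fusion sampling and every other
random stage; identical configuration and seed give bit-identical volumes,
samples and masks. The end-to-end demonstration (`run_demo()`) trains on 20
healthy phantoms and segments 10 lesioned plus 3 healthy subjects at 48³ —
sizes chosen so the whole study runs comfortably on a single CPU while every
stage operates in its intended regime; `quick = TRUE` drops to 32³ with
1.5–2.5 mm lesions for interactive use. Bank fitting pools intensities into
1-unit histogram bins before the kernel sums and weighted EM (quantisation
error is far below tissue noise); the public single-fit functions
`kernel_regress()` and `em_fit_two_component()` operate on the raw samples
and are the ones held to 1e-9 oracle agreement.

# Known limitations

* Hypointensity detection (lacunes) is out of scope: the hard zero below
  1000 restricts the mixture map to hyperintensities by construction.
* The one-class boundary at very small ν is sensitive to optimiser
  tolerance; the tightened default trades a few seconds of training time.
* Mean-field inference is approximate; it is validated against exhaustive
  enumeration only on tiny grids, and on large volumes the active-set
  restriction assumes background-certain unaries stay background — true for
  the bridge used here, not for arbitrary unaries.
* The phantom's periventricular geometry makes the whole WM shell fall
  within 15 mm of the ventricles, so the capping stage is exercised
  everywhere in WM; on real anatomy the shell is a minority of WM.
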