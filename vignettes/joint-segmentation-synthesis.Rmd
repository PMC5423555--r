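---
title: "Joint multi-atlas segmentation and pseudo-CT synthesis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint multi-atlas segmentation and pseudo-CT synthesis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(atlasfusion)
```

## The problem

Radiotherapy treatment planning needs electron-density information, which
CT provides directly (Hounsfield units map to attenuation) and MRI does
not.  An MRI-only workflow therefore has to synthesise a CT-like image — a
*pseudo-CT* (pCT) — from the MR images, and it also needs organ contours.
If segmentation and synthesis are solved independently, nothing guarantees
they agree: a voxel labelled bone can receive soft-tissue density.
`atlasfusion` implements a multi-atlas scheme that solves both problems
jointly, so that one per-voxel atlas weighting simultaneously produces the
pCT and the probabilistic organ segmentation, making the two consistent by
construction.

An *atlas* is one subject's co-registered set {T2-weighted MR, T1-weighted
MR, CT, manual segmentation}.  Given a target subject's T2 and T1, every
atlas is deformably registered to the target, its CT and labels are
propagated through the estimated transform, and the propagated values are
fused per voxel with weights derived from local image similarity.

## The iterative fusion model

At iteration $t$ the target dataset is
$\mathbb{I}_t = \{I^{T2}, I^{T1}, I^{pCT}_{t-1}, I^{S}_{t-1}\}$: the fixed
MR channels plus the pseudo-CT and probabilistic segmentation produced at
the previous iteration.  Each atlas $n$ is registered to this dataset and
propagated, giving $J^{T2}_{n,t}, J^{T1}_{n,t}, J^{CT}_{n,t}, J^{S}_{n,t}$.
The fused outputs are

$$I^{pCT}_t(x) = \frac{\sum_n w_{n,t}(x)\, J^{CT}_{n,t}(x)}
                      {\sum_n w_{n,t}(x)}, \qquad
  I^{S}_t(x,l) = \frac{\sum_n w_{n,t}(x)\, V_{n,t}(x,l)}
                      {\sum_k \sum_n w_{n,t}(x)\, V_{n,t}(x,k)},$$

where $V_{n,t}(x,l)$ is atlas $n$'s one-hot vote for label $l$ (from the
nearest-neighbour-propagated categorical labels; a fuzzy-vote mode using
linearly interpolated probabilities is available behind
`runConfig(voteMode = "fuzzy")`).  The weights apply an exponential decay
to the per-voxel similarity rank $r_{n,t}(x)$ (0 = locally most similar
atlas):

$$w_{n,t}(x) = e^{-\beta_t\, r_{n,t}(x)},$$

with $\beta_1 = 1$ decreasing by $0.125$ per iteration
(`betaSchedule()`), so later iterations — whose registrations are better —
average over more atlases.  Rank 0 is assigned weight 1 by construction,
which makes the fusion reduce to best-atlas copying as
$\beta \to \infty$ and to the unweighted mean as $\beta \to 0$; both
limits are verified numerically in the test suite.  The *same* weight
field drives both equations — this is the consistency guarantee, asserted
structurally in the tests.

At the first iteration no pseudo-CT or segmentation exists yet, so both
the registration and the similarity ranking use the MR channels only.

## Convolution-based local similarity over irregular FOVs

MR and CT acquisitions have different fields of view (different couches,
different extents), so local statistics computed near FOV borders with a
plain convolution would be biased.  All local moments are therefore
computed by *density-normalised convolution*: with $\Omega$ the binary
joint-FOV mask and $G_{\sigma_G}$ a Gaussian kernel,

$$\mu_I(x) = \frac{[G_{\sigma_G} * (I\,\Omega)](x)}
                  {[G_{\sigma_G} * \Omega](x)},$$

and analogously for second moments and covariances
(`normalizedMoments()`).  Voxels where the smoothed density falls below
$10^{-12}$ are flagged outside the usable field; similarity values there
are the sentinel $-\infty$ plus an explicit validity mask, which keeps
all downstream arithmetic NaN-free.

Three measures are built on these moments:

* **ROI-SSIM** (`roiSSIM()`): the product of the SSIM luminance and
  structure terms, bounded in $[-1, 1]$.  The stabilisers follow the SSIM
  convention $C_1 = (0.01 D)^2$, $C_2 = (0.03 D)^2$; the dynamic range $D$
  is fixed at 2000 HU for CT-like images and taken as the robust (1st to
  99th percentile) in-FOV range for MR.  When constants are derived for a
  pair, the larger range of the two is used so the measure remains
  symmetric.
* **LDSC** (`localFuzzyDice()`): a local fuzzy Dice between smoothed
  probabilistic segmentations, summed over labels.  Two conventions had
  to be fixed: a label with zero smoothed mass in both images contributes
  0 (absent labels must not inflate similarity), and the background label
  is excluded from the sum by default (it would otherwise dominate the
  score over the small organs).  Both are configurable.
* **LSIM** (`lsim()`): the plain sum ROI-SSIM(T2) + ROI-SSIM(T1) +
  ROI-SSIM(pCT$_{t-1}$, $J^{CT}$) + LDSC(S$_{t-1}$, $J^{S}$) for
  $t \ge 2$, MR terms only at $t = 1$.  The sum is implemented as written
  even though the LDSC term ranges over $[0, L']$ while ROI-SSIM is
  bounded by 1, making the channel balance scale-dependent; optional
  per-channel weights (default 1) expose the balance without changing the
  default behaviour.

$\sigma_G = 3$ is dimensionless in the framework's description; it is
interpreted here as **voxels** (configurable), which matches the usual
practice for normalised-convolution windows.  Kernels are truncated at
$3\sigma$; the truncation radius is part of the contract and the
brute-force test oracles use the same box support.

## Registration

The framework *configures* registration rather than contributing it: the
original study used NiftyReg.  No deformable registration engine exists in
the R ecosystem this package targets, so it ships a reference
implementation (`registerMultichannel()`) that is adequate for
phantom-scale volumes and deliberately modest:

* a global stage — symmetric-by-construction FOV-centroid translation,
  refined by Nelder-Mead on the channel cost (a 12-parameter affine
  refinement is available behind `globalMode = "affine"`);
* a multi-resolution cubic B-spline free-form deformation minimising the
  equally weighted sum of channel costs plus a bending-energy penalty on
  the control lattice, by gradient descent with a backtracking line
  search.  Linear interpolation is used during optimisation.

Channel costs are LNCC ($1 -$ mean local correlation, computed with the
same density-normalised moments) for monomodal intensity channels, a
sign-blind squared LNCC (`sim = "lncc2"`) for cross-modal pairs — the
local T2-CT intensity relation flips sign across tissues (bone is dark
on T2 and bright on CT), so the signed correlation would actively fight
alignment — and a Kullback-Leibler divergence (probabilities clamped to
$[10^{-6}, 1]$ and renormalised) for segmentation channels.

Three numerical safeguards matter in practice and are part of the
design:

* *Local-structure gating.*  Windows whose local variance falls far
  below the image's structured range (2% of the 98th-percentile window
  variance) are excluded from the correlation costs and forces.  In
  noise-flat regions the correlation of two images is pure noise, and
  especially the squared variant would otherwise reward deformations
  that "align" noise.  Full-resolution channels additionally receive a
  light density-normalised smoothing ($\sigma = 0.7$ voxels) for the
  same reason.
* *Segmentation forces from a smoothed surrogate.*  The KLD of
  near-one-hot label maps is piecewise flat — its exact gradient is
  zero almost everywhere and uninformative at label interfaces.  The
  descent direction therefore pushes each label's Gaussian-smoothed
  probability ($\sigma = 1.5$ voxels) toward the fixed one (a smoothed
  label-SSD force, demons-style), while the line search always
  re-scores the true KLD, so a step is only ever accepted if the actual
  objective decreases.
* *Structure-dominant weighting for multimodal problems.*  For the
  intra-subject database registrations the segmentation channel carries
  weight 3 and the cross-modal intensity channel weight 0.1.  Intensity-
  only multimodal non-rigid registration degrades alignment — the
  motivating study observed exactly this, and it is why the database
  construction is structure-guided in the first place; the weighting
  encodes that hierarchy (channel weights are configurable, equal
  weights remain the default of `registerMultichannel` itself).

Defaults follow the published operating points: finest control spacing
10 mm for inter-subject registration, 2.5 mm (T1$\to$T2) and 7.5 mm
(CT$\to$T2) for intra-subject database building, with a floor of three
working-voxels on coarse phantom grids; three pyramid levels (the
original used five for inter-subject registration of clinical volumes; on
64³ phantoms levels below 12³ carry no information and are skipped).
Within the pipeline, iteration $t+1$ warm-starts each atlas's
registration from its iteration-$t$ transform and revisits only the
finest level; this implements the framework's premise that registration
keeps improving across iterations, at a fraction of the cost of cold
restarts (a cold-start switch remains: `warmStart = FALSE`).  The
registration LNCC window is $\sigma = 2$ working-voxels truncated at
$2.5\sigma$ (the engine used originally does not document its window;
this choice balances capture range against cost on 64³ volumes).

Transforms are pull-back maps $x \mapsto A x + u(x)$ with the dense
displacement $u$ stored in mm on the fixed grid
(`SpatialTransform`); folding is monitored via the finite-difference
Jacobian determinant.  Grids must be axis-aligned for the reference
optimiser (all package-generated grids are); an external engine can be
plugged in by supplying its displacement fields through
`displacementTransform()`.

## Atlas database construction

Each subject enters as three image-segmentation pairs (T2, T1, CT, each
with manual contours).  `buildInitialRecord()` registers the T1 and CT
pairs to the T2 pair with LNCC on intensities **and** KLD on the
segmentations — structure-guided registration.  `buildDatabase()` then
optionally refines each CT-to-T2 mapping: leave-one-out synthesis
produces a pseudo-CT from the subject's T2 and a pseudo-T2 from its CT
(`synthesizeCrossModality()`, a single-pass ROI-SSIM-ranked fusion), and
`refineRecord()` re-registers {T2, T2-seg, pCT} against {pT2, CT-seg, CT}
with LNCC on the monomodal pairs, KLD on the segmentations, and a
preserved cross-modal T2-CT LNCC term.  The synthesis atlas set is the
*initial* records — the refined set does not exist yet.  Refinement
updates only the CT alignment; T2, T1 and the segmentation are never
touched, and the refinement warm-starts from (hence composes with) the
initial transform.  Finally the database is doubled by left-right
flipping with the femur-head labels swapped (`leftRightFlip()`), driven
by the lateral-pair declarations in the label dictionary.

## The phantom cohort

No clinical data accompany the method, so validation runs on a synthetic
pelvic cohort (`phantomSpec()`, `generateCohort()`): a left-right
symmetric template with an ellipsoidal body, a pelvic bone shell, paired
femur heads, bladder, prostate and a bent rectal tube, rendered into CT
(air $-1000$, soft tissue $\approx 30$, bone $700$–$1000$ HU) and
T1/T2 (per-tissue means chosen for plausible contrast: urine bright on
T2 and dark on T1, bone dark on both, femur-head marrow bright on T1)
with additive Gaussian noise (MR sd 3 a.u., CT sd 15 HU), a smooth
multiplicative MR bias field (±10%), and an MR FOV deliberately cropped
relative to the CT FOV.  Subjects are the template warped by random
cubic-B-spline fields (coefficient sd 3 mm at 32 mm spacing, folding
guarded by halving) plus a per-subject rectal filling change, with ±3%
per-tissue intensity jitter.  The deformations live in the same B-spline
family the registration optimises — deliberately easy, so registration
failures indicate bugs rather than model mismatch; the amplitude still
leaves the per-iteration registration unconverged, which is the regime
the iterative scheme addresses.  Everything is deterministic under
(spec, N, seed), and the true warps are returned for endpoint-error
oracles.

What passing phantom tests do *not* show: realistic MR physics (no
spatially correlated noise, no susceptibility or chemical-shift effects),
real inter-subject anatomical topology changes, couch differences beyond
FOV cropping, or clinical-grade registration difficulty.  Results on
phantoms validate the machinery, not clinical accuracy.

## Evaluation suite

`fuzzyDice()` (Zadeh min/sum form, reducing to hard Dice on one-hot
input), `modifiedHausdorff()` on 6-connectivity boundary voxel centres
(in mm), `maeMe()` (MAE and signed ME in HU over a ROI), `nmi()`
(64-bin joint histogram), and the water-only baseline `waterOnlyPct()`
(threshold, 3-D hole fill, 0 HU body / $-1000$ HU air).  On calibrated
HU a $+500$ threshold would segment only bone, so the default body
threshold is $-500$ HU with the literal $+500$ available for
offset-intensity conventions.  The bone ROI on phantoms comes from the
generator's true bone mask.

## Numerical choices and degenerate inputs

* Variances from moment differences are clamped at zero (tolerance
  $10^{-9}$); density denominators below $10^{-12}$ mark a voxel outside
  the field.
* Ranking ties break towards the lower atlas index; argmax ties towards
  the lower label index.  Both make the pipeline bit-deterministic.
* Voxels where no atlas has finite similarity are "unfusable": the pCT
  policy fills air outside the target body mask and propagates the
  nearest fusable value inside it; the segmentation falls back to
  background; a QA mask records them.
* Probabilistic propagation with linear interpolation renormalises the
  simplex; nearest-neighbour propagation preserves one-hot exactness.
* `betaSchedule()` floors at $0.125$ so runs beyond seven iterations keep
  a positive decay.

## Problem sizes

The shipped studies use 64³ voxels at 2.5 mm (cohorts of 8 for the
leave-one-out study; held-out target extra) and 48³ at 3.33 mm with 4
subjects for the refinement study; these sizes were chosen so the full
suite runs on a single CPU in minutes while keeping organs several
similarity-kernel widths across.  Default pipeline effort is
`maxIter = c(8, 6, 4)` descent iterations per pyramid level and 6
warm-start iterations at the finest level; four pipeline iterations is
the recommended operating point, two suffice to demonstrate the
improvement trend on phantoms.

## Known limitations

The reference registration is not NiftyReg and makes no bit-compatibility
claims; its symmetric global stage is symmetric only in the centroid
term.  N4-style bias-field correction is out of scope (a hook,
`biasCorrectionHook()`, accepts an external corrector).  DICOM input,
dose calculation and DVH analysis are out of scope.  The LSIM channel
balance question (unit-weight sum over channels with different ranges) is
resolved by following the published form; the optional channel weights
exist for sensitivity analyses.
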