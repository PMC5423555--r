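# atlasfusion

Joint multi-atlas segmentation and pseudo-CT synthesis for MRI-only
radiotherapy treatment planning.

## The problem

Radiotherapy planning needs two things that are usually read off a CT
scan: organ-at-risk contours and electron densities (Hounsfield units).
MRI gives far better soft-tissue contrast for contouring but no density
information, so an MRI-only workflow must synthesise a *pseudo-CT* (pCT)
from the MR images — and the synthesised densities must agree with the
contours (a voxel labelled bone must have bone density).  `atlasfusion`
implements an iterative multi-atlas information propagation framework
that solves segmentation and CT synthesis *jointly*, for the male pelvis
(prostate, bladder, rectum, femur heads) from T2- and T1-weighted MR.

## The method in brief

Each atlas is a co-registered subject dataset
`{I_n^T2, I_n^T1, I_n^CT, I_n^S}`.  At iteration *t*, every atlas is
deformably registered to the evolving target dataset
`{I^T2, I^T1, I_{t-1}^pCT, I_{t-1}^S}` (MR channels only at *t* = 1),
propagated, and fused per voxel:

    I_t^pCT(x) = Σ_n w_{n,t}(x) J_{n,t}^CT(x) / Σ_n w_{n,t}(x)
    I_t^S(x,l) = Σ_n w_{n,t}(x) V_{n,t}(x,l) / Σ_k Σ_n w_{n,t}(x) V_{n,t}(x,k)
    w_{n,t}(x) = exp(−β_t · r_{n,t}(x)),   β_1 = 1, decreasing by 0.125

where `r_{n,t}(x)` ranks the atlases at voxel `x` by a local similarity
(LSIM) summing FOV-aware structural similarity (ROI-SSIM) on the MR and
CT channels and a local fuzzy Dice (LDSC) on the segmentation channel,
all computed by density-normalised Gaussian convolution so that differing
MR/CT fields of view do not bias the local statistics.  One weight field
drives both fusions, which is what makes the pCT and the labels
consistent.  The package also implements the atlas-database construction
scheme (structure-guided intra-subject registration plus pseudo-CT /
pseudo-T2 refinement of the CT-to-T2 mapping and left-right flip
augmentation), a reference multi-channel B-spline registration
(LNCC + KLD channels), the evaluation suite (fuzzy Dice, modified
Hausdorff distance, MAE/ME, NMI, water-only baseline), and a synthetic
pelvic phantom cohort generator with ground-truth warps.

## Worked example

A complete run on a synthetic cohort (a minute or two on one CPU):

```r
library(atlasfusion)

co  <- generateCohort(phantomSpec(size = 48L, spacing = 10/3), N = 4, seed = 5)
cfg <- runConfig(nIterations = 2)
res <- runPipeline(t2Volume(co$target$record), t1Volume(co$target$record),
                   co$db, cfg)

# compare against the phantom's ground truth
truth <- co$target
body  <- labelArray(truth$labels) > 0L
maeMe(res$pct, ctVolume(truth$record), body)
#>       mae        me
#> 45.024840 -9.532561
sapply(1:5, function(l) fuzzyDice(segVolume(truth$record), res$segProb, l))
#> [1] 0.9598113 0.9922963 0.8563027 0.9967523 0.9906931
res$log[, c("iteration", "beta", "nAtlases", "meanBestLsim")]
#>   iteration  beta nAtlases meanBestLsim
#> 1         1 1.000        4     1.650144
#> 2         2 0.875        4     4.252278
```

The MAE/ME line says the synthesised pseudo-CT is within ~45 HU of the
reference CT on average inside the body with a -10 HU bias; the five
numbers are fuzzy Dice overlaps for prostate, bladder, rectum and the
two femur heads; the log shows the rank-decay β per iteration and the
mean similarity of the locally best atlas, which rises as the
registrations and the target state improve.

A thin CLI over the same functions lives at `inst/cli/atlasfusion.R`
(`phantom`, `run`, `loo`, `evaluate` subcommands).

## Package tour

| Area | Functions |
|---|---|
| Image model & I/O | `scalarVolume`, `probSegVolume`, `readVolume`, `writeVolume`, `resampleIsotropic`, `leftRightFlip`, `biasCorrectionHook` |
| Similarity | `normalizedMoments`, `roiSSIM`, `localFuzzyDice`, `lsim` |
| Fusion | `betaSchedule`, `rankAtlases`, `weightsFromRanks`, `fuseIntensity`, `fuseLabels`, `categoricalFromProb` |
| Registration | `registrationSpec`, `registerMultichannel`, `applyTransform`, `lnccCost`, `kldCost` |
| Atlas database | `buildInitialRecord`, `synthesizeCrossModality`, `refineRecord`, `buildDatabase`, `writeDatabase`/`readDatabase` |
| Pipeline | `runConfig`, `runIteration`, `runPipeline`, `leaveOneOut` |
| Evaluation | `fuzzyDice`, `modifiedHausdorff`, `maeMe`, `nmi`, `waterOnlyPct`, `metricReport` |
| Phantoms | `phantomSpec`, `generateTemplate`, `generateCohort`, `misalignRecord` |

The methods vignette
(`vignettes/joint-segmentation-synthesis.Rmd`) documents the model, the
numerical conventions, the phantom design and the known limitations.
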