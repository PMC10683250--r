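---
title: "Parametric response mapping and inspiratory-only PRM prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric response mapping and inspiratory-only PRM prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lungprm)
```

## The PRM model

Parametric response mapping (PRM) classifies every lung voxel of a
co-registered inspiratory/expiratory CT pair by its joint attenuation:

* **fSAD** (functional small airway disease): inspiratory attenuation
  above −950 HU and expiratory attenuation below −856 HU — the voxel
  looks normal at full inspiration but fails to regain density at
  expiration, the imaging signature of non-emphysematous air trapping;
* **emphysema**: below −950 HU at inspiration *and* below −856 HU at
  expiration — tissue destruction visible in both phases;
* **normal parenchyma**: everything else inside the lung.

`classify_prm()` implements the rule; `prm_fractions()` reports the
volume percentages PRM^Normal, PRM^fSAD and PRM^Emph over the lung.
Two whole-lung companions are included because they are the standard
non-spatial air-trapping indices: `laa856()` (percentage of expiratory
lung voxels below −856 HU) and `ei_ratio()` (mean expiratory over mean
inspiratory lung attenuation).

**Boundary convention.** The defining inequalities are strict, which
leaves integer HU values exactly at a cut undefined. We classify
inspiratory attenuation equal to −950 HU into the fSAD branch (it is
not "below −950") and expiratory attenuation equal to −856 HU as not
trapped. Both conventions are fixed, documented in
`?prm_thresholds`, and covered by tests.

## The synthetic phantom

Because paired clinical inspiratory/expiratory cohorts are not freely
available, the package ships a phantom generator
(`phantom_spec()`, `generate_phantom()`) that reproduces the
*attenuation logic* the PRM rule relies on. A body ellipsoid (+40 HU)
contains two lung ellipsoids whose interior is partitioned into normal
parenchyma, fSAD and emphysema by unions of random ellipsoidal blobs
(semi-axes 4–9 voxels by default, i.e. lesions of roughly 1–2 cm at
the default 2 mm spacing), placed greedily until the realized class
fractions sit within ±3 percentage points of the targets (defaults:
20% fSAD, 5% emphysema — the range in which SAD stratification
thresholds are discussed clinically).

Noiseless class means (HU, inspiratory / expiratory) are
normal −880 / −700, fSAD −880 / −900, emphysema −975 / −965, with
background −1000. The means sit away from both decision cuts so that
label purity is controlled by the additive Gaussian noise
(`noise_sd`, default 10 HU): the tightest margin (fSAD expiratory,
44 HU) is 4.4 standard deviations, giving a per-voxel flip
probability of a few in a million, while the emphysema inspiratory
margin (25 HU, 2.5 sd) admits a fraction of a percent of flips —
comparable to the label noise real PRM incurs near −950 HU.

**Expiration model.** The expiratory volume is the density-shifted
inspiratory volume displaced toward the inferior face of the grid:
each axial column moves by `(compression − 1) * (apex height)` voxels
(default compression 0.90, about 4–5 voxels ≈ 1 cm at the default
geometry — conservative against real diaphragmatic excursion),
composed with a smooth random in-plane perturbation (amplitude ≤ 2
voxels, coarse control grid). The total shift is **rounded to whole
voxels and kept constant along each column**. This quantization is a
deliberate design choice: the phantom's ground truth must be exactly
recoverable by `classify_prm()` after warping the expiratory volume
back with the true field, and a *continuous* deformation of a
piecewise-constant image cannot achieve that — trilinear resampling
mixes the class means at lesion boundaries, and any mixture of
−700 (normal) and −900 (fSAD) crosses the −856 HU cut. With integer
displacements the warp is an exact lookup, so the zero-noise
round-trip reproduces the construction labels on 100% of lung voxels.

**What the phantom does not emulate.** Real parenchyma has vascular
and septal texture; the phantom's tissue classes are homogeneous.
Two consequences matter for interpreting results. First, registration
of real lungs is anchored by texture everywhere, whereas phantom
registration is anchored only at lung borders and lesion borders.
Second — and more fundamental — phantom fSAD carries **no inspiratory
signature at all**: its inspiratory mean equals that of normal
parenchyma and lesion placement is random. An inspiratory-only
predictor therefore has zero information about *where* fSAD is, the
Bayes-optimal voxel decision in parenchyma is "normal", and held-out
fSAD overlap of the learned model is at chance. In the clinical
setting the method's premise is precisely that inspiratory texture
*does* carry fSAD signal; passing phantom tests consequently
demonstrates the machinery (losses, thresholds, fusion, inference)
end-to-end, but says nothing about fSAD localization performance on
real data. The emphysema pathway, which is visible at inspiration, is
the phantom's informative end-to-end probe.

## Registration

`register_ffd()` aligns the expiratory scan onto the inspiratory grid
with a multi-resolution cubic B-spline free-form deformation,
minimizing a masked mean-squared HU error by gradient descent on the
control-point displacements (step halved on non-improving steps, so
accepted steps never increase the objective; a level stops when the
relative improvement falls below `tol` or its iteration cap is
reached). Defaults: three levels with control spacing 16, 8 and 4
voxels, 40 iterations per level.

Two additions to the plain MSE scheme proved necessary and are both
config-exposed:

* **Bending-energy regularization** (`reg_weight`, default 1e4): the
  squared discrete Laplacian of the control grid. Across phases the
  parenchyma changes density systematically (normal lung −880 HU at
  inspiration vs −700 HU at expiration, but trapped lung −900 HU), so
  an unregularized MSE optimum *expands* expiratory trapped regions
  over normal lung — a deformation that "explains" intensities while
  destroying the anatomy. On phantoms this failure is fully
  expressed (fSAD overlap drops to 0.35 and the field error grows to
  several voxels); the bending term suppresses the voxel-scale part
  of it while leaving smooth respiratory motion essentially free.
* **Dilated metric mask** (`mask_dilate`, default 3 voxels): with a
  lung-only mask the inferior lung–body interface cannot anchor the
  field, because the body side of the interface is excluded from the
  metric and sliding inside homogeneous lung is MSE-neutral; we
  measured a systematic ~2-voxel under-displacement at the lung base.
  Supporting the metric on the slightly dilated mask anchors the
  interface from both sides. The reported before/after MSE always
  uses the undilated lung mask.

With both in place the estimated field recovers the phantom's true
field to ~0.4 voxel median error and PRM computed through the
estimated field reaches fSAD Dice ≈ 0.9 against the construction
labels.

`warp_volume()` applies a dense displacement field (defined on the
fixed grid, voxel units) by trilinear interpolation, filling
out-of-grid samples with −1024 HU.

## The networks

The inspiratory-only pathway uses two stages built from a common
UNet-like backbone (two 3×3×3 convolutions per resolution level,
leaky-ReLU activations, 2× average pooling, nearest-neighbour
upsampling with skip concatenation; no normalization layers):

1. **Expiratory generator** (`train_expiratory_generator()`): a
   coarse generator G1 maps an inspiratory patch to an expiratory
   patch (residual-style, so it starts from the identity), a
   conditional refiner G2 maps (inspiratory, coarse expiratory) to a
   refined patch (exactly the identity at initialization), and both
   share one conditional patch discriminator. Each generator is
   supervised by `lambda_l1` (default 100) times its mean absolute
   error plus the adversarial term (least-squares by default;
   cross-entropy available).
2. **PRM generator** (`train_prm_generator()`): a UNet over
   (inspiratory, expiratory) patches with three heads — per-voxel
   class logits, a per-voxel HU residual added to the expiratory
   channel, and a two-layer MLP on the global-average-pooled
   bottleneck that outputs a *learnable expiratory threshold* as an
   offset from −856 HU (zero-initialized, so training starts exactly
   at the conventional cut; the inspiratory cut stays fixed at −950).
   The losses are the lung-masked class-weighted cross-entropy
   against the ground-truth PRM, `lambda_consistency` (default 1)
   times the consistency loss between the segmentation probabilities
   and the soft threshold PRM (`soft_threshold_prm()`, temperature
   `soft_tau` = 20 HU), and `lambda_residual` (default 1) times a
   lung-masked L1 on the residual-corrected expiratory patch.

At inference (`predict_prm()`) the volume is tiled into overlapping
patches blended with a cosine window, the residual-corrected
generated expiratory volume is hard-thresholded at the learned cut,
and the final map averages the segmentation probabilities with the
one-hot threshold PRM (`fuse_prm()`; ties break
normal > fSAD > emphysema).

### Training recipe choices

These were settled by measurement during development and are all
exposed in `net_config()`:

* **Intensity units** are standardized as (HU + 800) / 200, centring
  parenchymal values near zero. With a naive HU/1000 scaling the
  class-discriminative contrast is ~0.1 on top of a large common
  offset and the segmenter barely moves in the few hundred optimizer
  steps a CPU-scale run affords.
* **The residual L1 is restricted to the lung** and weighted 1, not
  higher: outside the lung the expiratory channel needs no
  correction, and unmasked sign-gradients over the ~90% non-lung
  patch voxels drown the segmentation gradient in the shared trunk.
* **The threshold MLP trains at 0.1× the base rate**
  (`lr_threshold_factor`). The consistency term couples a scalar to
  the whole segmenter; at equal rates the pair can co-adapt
  degenerately (the threshold drifts until the threshold PRM is
  all-normal, which then drags the segmenter with it).
* **Class weights** (1, 1, 8): emphysema occupies a few percent of
  the lung; up-weighting this rare but *unambiguous* class speeds its
  learning without moving the decision boundary. fSAD is left at
  weight 1 — up-weighting an ambiguous class would shift the
  parenchymal argmax rather than add information.
* Package defaults keep the conventional image-translation settings
  (3 levels, 16 base channels, Adam at 2e-4 with β₁ = 0.5, 48³
  patches). The scaled-down experiments in the test suite and the
  acceptance script use 2 levels with 2–4 base channels, one patch
  per volume per epoch, 5–30 epochs, and a 2e-3 rate — sizes chosen
  so a complete train/evaluate cycle runs on one CPU core in minutes.
  The stated quality bars (emphysema Dice, fraction correlation,
  decreasing generator L1, threshold stability) are met at these
  sizes; fSAD localization is at chance for the structural reason
  given above.

## Stratification

`binarize_fsad()` labels a subject as significant SAD when PRM^fSAD
strictly exceeds the chosen threshold (15–25% is the clinically
discussed band). `roc_auc()` computes the ROC over all distinct score
thresholds (trapezoidal AUC, equal to the Mann–Whitney statistic with
ties counted ½) and `youden_cutoff()` selects the operating point
maximizing sensitivity + specificity − 1, resolving ties toward the
lower threshold. Youden's J is our choice of cut-off criterion; the
selection rule behind published cut-offs is typically unstated, and J
is the standard reading when sensitivity and specificity are reported
together.

## Numerical notes and degenerate inputs

* All volumes are clamped to the 12-bit CT range [−1024, 3071] HU on
  ingest; masks and label maps bypass clamping.
* `classify_prm()` refuses mismatched grids and empty masks; fraction
  computations refuse empty lungs; `ei_ratio()` refuses a zero mean
  inspiratory attenuation.
* Thresholding a trilinearly warped volume can misclassify lesion
  boundary voxels (interpolated values cross the cuts); the phantom's
  whole-voxel true field avoids this for ground truth, and the
  registration tests quantify it for estimated fields.
* Dice returns 1 when a class is absent from both maps; the fusion
  tie-break and the boundary conventions above make every pipeline
  output deterministic. Training is deterministic given a seed
  (single-threaded BLAS; R's RNG drives initialization, patch
  sampling and shuffling).

## Known limitations

* The phantom has no intra-class texture, no airways or vessels, and
  no scanner physics; its registration and fSAD conclusions transfer
  to real data only as far as stated above.
* The FFD is not guaranteed diffeomorphic and no inverse field is
  computed.
* Global single-window SSIM is reported (the form matching the
  definition used for this pipeline), not the sliding-window variant;
  the two are not comparable numerically.
* Networks are small CPU-scale models; no attempt is made to match
  cohort-trained GPU results.
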