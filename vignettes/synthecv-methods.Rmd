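---
title: "Methods: automated synthetic-ECV quantification and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated synthetic-ECV quantification and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement model

Myocardial extracellular volume (ECV) is estimated from paired native and
post-contrast T1 maps under the standard two-compartment equilibrium
assumption: about 15 minutes after gadolinium administration the contrast
concentration in the myocardial extracellular space tracks that of blood
plasma, so the ratio of contrast-induced relaxation-rate changes
(ΔR1 = 1/T1_post − 1/T1_native) in myocardium versus blood, scaled by the
plasma fraction (1 − HCT), yields the extracellular fraction:

ECV = (1 − HCT) · ΔR1_myo / ΔR1_blood.

`compute_ecv()` implements exactly this; "synthetic" ECV is the same
computation with the laboratory hematocrit replaced by a linear regression
of HCT on native blood-pool R1 (red cells shorten blood T1, so R1 carries
hematocrit information). The regression is stratified by sex and field
strength; `fit_hct_model()` calibrates the strata from data, and
`hct_model()` accepts externally published coefficients. Predictions are
clamped to (0.05, 0.70) and flagged outside (0.15, 0.60), so a corrupted
blood median cannot silently produce a nonsense plasma fraction.
A non-positive blood ΔR1 ("contrast washout reversed") is an error; a
negative myocardial ΔR1 only warns, since the ECV sign itself is the
diagnostic signal there.

## The measurement chain and its parameters

1. **Segmentation** produces three masks per map: epicardial (full LV disc),
   endocardial (cavity *including* papillary muscles — the contour
   convention; their removal belongs to refinement), and RV cavity. All
   backends — `segment_oracle()` (phantom ground truth), `segment_classical()`
   (intensity-based), `segment_learned()` (trainable) — emit the same
   validated structure, so downstream stages are backend-blind.
2. **Refinement** (`refine_all()`): myocardial ring = epicardium ∖
   endocardium, then one pass of 3×3 binary erosion (a voxel survives iff
   its full 8-neighborhood is in the mask; raster edges count as outside).
   A single pass removes exactly one voxel along both margins, which is the
   intended mitigation of partial-volume contamination at motion-uncorrected
   borders. The blood pool is separated from papillary muscles by Otsu's
   threshold computed *inside the endocardial mask only*, then eroded the
   same way. Two-voxel-thin walls erode to nothing and raise a stage-named
   error rather than returning an empty median.
3. **Quantification**: `median_t1()` (even counts average the central pair),
   `predict_hct()`, `compute_ecv()`, `classify_ecv()` with thresholds 0.30
   and the adapted 0.295 for synthetic ECV. The boundary counts as
   positive (ecv ≥ threshold); the convention is fixed so McNemar results
   are reproducible.

Key defaults: erosion kernel 3×3 (one voxel); Otsu histogram 256 bins over
the observed in-mask range, ties broken toward the lower threshold;
unimodality fallback when between-class variance is below 1 % of total
variance (a homogeneous cavity is returned whole rather than split in
half); thresholds (0.30, 0.295) as fractions. ECV is a fraction internally
and percent only at reporting, preventing silent 100× errors.

Decisions the source design left open, resolved here:

* Otsu is computed per phase on the map being measured (native and post
  contrast regimes differ; reusing a native threshold on a post map has no
  physical basis). The blood class is *above* threshold on native maps and
  *below* on post-contrast maps, following gadolinium physics.
* The "one-voxel shrinkage" of contours and the 3×3 erosion are one and the
  same operation, not two sequential steps.
* The LV blood pool supplies both ECV blood terms and the synthetic-HCT
  predictor; RV-calibrated models are expressible through the model's
  chamber stratum.
* The synthetic-HCT regression uses R1 (= 1000/T1 ms, in 1/s) as the
  predictor; a model on T1 directly can be emulated through the coefficient
  slot since the pipeline never constrains the sign of β.

## The classical backend

The model-free backend resolves background < myocardium < blood on the
native map. Rather than a single three-class Otsu pass it uses two stages:
first tissue vs background, then myocardium vs blood within tissue. The
reason is partial volume: mixed boundary voxels form a thin but genuine
intensity mode between background and myocardium, and when
myocardium/blood contrast is low a one-shot three-class optimum collapses
onto {background | mixed | all tissue}, merging the wall into the cavity.
The second stage therefore also excludes the one-voxel background-adjacent
shell from its histogram. The LV cavity is chosen among high-T1 components
by isoperimetric circularity (4πA/P² ≈ 1 for a disc, far lower for the RV
crescent) — shape, not size, because the RV can rival the cavity in area;
papillary muscles re-enter the endocardial mask by hole filling; the ring
is the adjacent mid-class component (with its shell restored); the RV is
the largest remaining high component plus its directly adjacent
partial-volume band. All components are 8-connected, matching the 3×3
structuring element.

## The learned backend (optional, scaled down)

The reference design trains a full encoder–decoder segmentation network
per contrast phase. No deep-learning framework is available in this
package's dependency set, so the training path is demonstrated with a
deliberately small stand-in: a multinomial elastic-net pixel classifier
(glmnet) on per-image z-score-normalized intensity plus spatial features
[z, y, x, y² + x²]. Linear boundaries in these features are circles of
arbitrary center and radius combined with intensity thresholds — sufficient
for short-axis anatomy, and honest about being a 0-hidden-layer "network".
Separate models per phase, balanced pixel subsampling (300/class/image),
ridge-leaning penalty fit along a decreasing λ path (noiseless cohorts are
perfectly separable and diverge otherwise), all deterministic under the
stored seed. Its argmax output passes through the same largest-component /
hole-filling cleanup and mask validation as every other backend. The
default pipeline never requires it.

## What the phantom emulates — and what it does not

`generate_cohort()` renders 128×128 short-axis scenes at 1.17 mm isotropic
spacing (the stated "1.17 mm²" voxel is read as edge length and is
configurable): LV cavity, myocardial ring, two papillary discs inside the
cavity, and an RV crescent. Per-subject truths are drawn from the source
cohort's statistics: HCT ~ 42.6 ± 5.4 % truncated to [20, 60] %, ECV ~
27.2 ± 6.0 % truncated to [10, 55] %, native myocardial T1 1036 ± 60 ms
(1.5 T) / 1270 ± 60 ms (3 T), post-contrast blood T1 311 ± 58 / 330 ± 47
ms, field mix 59 % at 3 T, 61 % male. Native blood T1 follows
R1 = c0 + c1·HCT with (c0, c1) = (0.262, 0.90) at 1.5 T and (0.335, 0.50)
at 3 T — chosen so the marginal blood-T1 distributions land on the reported
~1559 ± 121 and ~1839 ± 90 ms (the quadratic Jensen correction of 1/R1
raises the mean ~6 ms above 1/E[R1]) — plus a small sex offset in c0
(±0.01) so sex-stratified models are genuinely distinct, and residual R1
noise of 0.008 s⁻¹ so calibration is a statistical, not algebraic,
exercise. The post-contrast myocardial T1 is *solved* from the ECV relation
given the other truths, so in a noise-free world the pipeline must return
ecv_true to machine precision — the ground-truth closure every oracle-mask
test asserts.

Degradations: voxelwise Gaussian noise with SD = 2 % of the tissue value
(maps, not raw complex images, are the input — hence Gaussian, not
Rician), and a one-voxel partial-volume band mixing each boundary voxel
50/50 with the mean of its differing neighbors. "Ideal" in the tests means
both disabled; the noisy acceptance world keeps both.

Not emulated: pulse-sequence systematics (MOLLI fitting bias, inversion
imperfections), motion and foldover artifacts, pathology-driven regional
heterogeneity (infarct, amyloid), septal-vs-lateral T1 gradients, 3-D
geometry, and the heavy right tail of clinical ECV. A green phantom test
therefore establishes algorithmic correctness of the measurement chain —
not clinical performance; the cohort-level clinical agreement figures
require patient data and are out of reach by construction.

Numerical geometry choices worth knowing: voxel membership is decided by
the voxel center with inclusive boundaries; rasterized areas match analytic
areas within 5 % for the annulus and for discs of radius ≳ 7 mm, but
lattice-counting fluctuations exceed 5 % for discs as small as exactly
5 mm — the area oracle is asserted at the package's papillary scale (8 mm).
The LV–RV background gap is 4.7 mm (≥ 3 voxel layers): with less, the
one-voxel partial-volume layers from either side meet and the two blood
pools fuse at raster resolution, which is a well-posedness constraint of
the scene, not a tuning knob.

## Agreement statistics

All validation statistics are implemented against small-instance oracles:
Bland–Altman with 1.96-normal limits of agreement (the conventional
presentation), t-based CI for the bias (SE = SD/√n) and the large-sample
SE = SD·√(3/n) for each limit's CI — the exact-t variant was not claimed by
the source and the choice is documented, not asserted; stratified reports
split on the *pair mean* (reference ≤ / > 35 %). Pearson and two-sided
paired t tests; concordance tables with McNemar's test, defaulting to the
continuity-corrected χ² = (|b−c|−1)²/(b+c) — the variant that reproduces
both published p-values (0.635 from discordant counts 18/22 and 0.024 from
14/30) exactly, where the exact binomial gives 0.636 for the first;
ICC(2,1)/ICC(2,k) from two-way ANOVA mean squares (absolute agreement, no
imputation of missing cells); Dice; and the classic maximum Hausdorff
distance over boundary-voxel centers (no 95th-percentile variant, which the
source did not claim). With one empty mask Dice is 0 by definition while
the Hausdorff distance is undefined and returned as NA with a warning.

## Known limitations

* The phantom's partial-volume model is a single mixed band; real maps blur
  over a point-spread function several voxels wide.
* The classical backend assumes the native contrast ordering background <
  myocardium < blood and a roughly circular cavity; it is a test double for
  the pipeline, not a clinical segmenter.
* The learned backend's spatial features presume a roughly centered heart;
  it demonstrates the training path, nothing more.
* Synthetic-HCT models calibrated on the phantom inherit the phantom's
  linear R1 coupling; with patient data the same code fits whatever linear
  relation the site's scanner produces, and nonlinearity would surface as
  residual SD in the model diagnostics.
* NIfTI support is a minimal purpose-built 2-D codec (no NIfTI package
  exists in the supported dependency set): single-file NIfTI-1, float32 /
  uint8, pixdim spacing, scl scaling, both endiannesses — not a general
  neuroimaging reader.
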