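---
title: "Methods: two-stage radiomics for IDH mutation prediction"
author: "GliomaRadiomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-stage radiomics for IDH mutation prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the pipeline

Isocitrate dehydrogenase (IDH) mutation status is a key prognostic marker
in glioma, and it can be predicted noninvasively from preoperative MRI.
`GliomaRadiomics` implements a complete radiomics pipeline for that task:

1. **ROI construction** from a labeled tumor segmentation, under three
   label schemes (FeTS: 1 = NCR, 2 = NET/ED, 4 = ET; UCSF: 1 = NET/NCR,
   2 = ED, 4 = ET; or a binary whole-tumor mask).  Two regions are used
   everywhere: the whole tumor (WT, ROI1) and the nonenhancing region
   (NET + NCR + ED, ROI2) — the tumor minus its enhancing component.
   Using these two composite regions (rather than individual
   subcompartments) keeps every patient in the cohort even when a
   subcompartment is absent.
2. **Filtered-image generation**: 12 derived images per MRI sequence —
   four undecimated wavelet subbands (LL/LH/HL/HH), Laplacian of Gaussian
   at sigma = 2, 3, 4, 5 mm, and four monotone intensity transforms
   (square, square root, logarithm, exponential).
3. **Feature extraction**: seven classes per ROI per sequence — 14 shape
   features on the original geometry, plus 18 first-order, 22 GLCM,
   16 GLRLM, 16 GLSZM, 14 GLDM and 5 NGTDM features on the original and
   every derived image: 14 + 91 x 13 = **1197 features per (ROI,
   sequence)**, 9576 per patient with both ROIs and four sequences.
4. **Feature selection**: Boruta shadow-feature testing, run on multiple
   balanced subsets of the training data; features confirmed in at least
   a threshold fraction of subsets form the relevant set.  Selection is
   run per ROI and on the combined ROI pool.
5. **Two-stage classification** for the class imbalance (mutated tumors
   are the minority, about 27% prevalence): stage one draws balanced
   subsets by undersampling the majority class to exactly 1:1 and fits
   one classifier (random forest or gradient boosting) per subset; stage
   two averages the member probabilities.  A SMOTE oversampling
   comparator is included.
6. **Evaluation**: accuracy, sensitivity, specificity, precision, F1,
   ROC/AUC by the rank (Mann-Whitney) formulation, and DeLong
   placement-value variance with normal-approximation confidence
   intervals.

Inputs are assumed preprocessed: coregistered, 1 mm isotropic,
skull-stripped NIfTI volumes for T1, postcontrast T1, T2 and T2-FLAIR,
with a coregistered integer-labeled segmentation.  Registration, bias
correction and automated segmentation are deliberately out of scope.

## Key numerical and design choices

**Discretization.** Fixed bin width (default 25 intensity units) anchored
at the ROI minimum: `level(x) = floor((x - min)/w) + 1`.  Fixed bin width
is the standard radiomics default; it keeps bin boundaries comparable
across patients on comparably scaled inputs.  All texture classes are
computed on the discretized ROI.

**Texture aggregation.** GLCM and GLRLM are computed per direction over
the 13 unique 3D offsets at Chebyshev distance 1 and feature values are
averaged across directions; GLSZM zones use 26-connectivity; GLDM uses
the 26-neighborhood with similarity tolerance alpha = 0 and counts the
center voxel in the dependence size (sizes 1..27); NGTDM uses the
26-neighborhood mean difference, excluding voxels with no in-ROI
neighbor.  The 22 GLCM features are the canonical co-occurrence set
(without the matrix correlation coefficient MCC).

**Degenerate conventions.** A constant ROI yields Correlation = 1,
entropies = 0, Skewness = Kurtosis = 0, Uniformity = 1, and NGTDM
Coarseness capped at 1e6.  These conventions avoid NaNs that would
silently poison downstream selection; they are recorded in the
extraction configuration (`defaultExtractionConfig()`).

**Laplacian of Gaussian.** The sigma values are in millimetres and are
converted to voxel units through the image spacing.  The kernel is the
analytically sampled 3D LoG, evaluated as the sum of its three separable
axis terms and truncated at six sigma per axis — wide enough that the
impulse response matches the tabulated analytic kernel to better than
1e-6 of the peak.  Boundaries are mirror-padded.  A sigma below half the
largest voxel dimension triggers an under-resolution warning, not an
error.

**Wavelets.** "Four wavelet images" is implemented as a one-level
undecimated 2D transform applied slice-wise along the axial axis with
periodic boundaries, yielding LL/LH/HL/HH volumes of the original shape.
The family is configurable (coif1 default; haar and db2 available); the
filter coefficients are the standard published banks.  A 3D eight-subband
decomposition would yield eight image types, which is inconsistent with
the four wavelet image types the pipeline expects, so it is a non-goal.

**Intensity transforms.** All four are rescaled so the output
maximum-absolute-value equals the input's: square `x^2/m`, square root
`sign(x) sqrt(m |x|)`, logarithm `sign(x) m log(|x|+1)/log(m+1)`,
exponential `exp(x log(m)/m)`, with `m = max |x|`.  On MRI-scaled inputs
(m > 1) all four are strictly increasing, so they preserve intensity rank
order inside the ROI; an all-zero volume maps to all-zero outputs.

**Shape surface mesh.** Surface area and mesh volume come from a
marching-tetrahedra isosurface with linear edge interpolation.  Meshing
the raw binary mask overestimates the area of digitized objects by
10-30% (the staircase effect), so the mask indicator is first smoothed
with a Gaussian of 0.8 voxels and meshed at level 0.5 — a standard
anti-aliasing step.  On a digitized ball of radius 10 voxels this gives
surface area within about 1% of the analytic value and sphericity about
0.99.  ROIs too small to survive the smoothing fall back to the binary
mesh with a warning.  Axis lengths are `4*sqrt(lambda)` from the
principal moments of the physical voxel coordinates; diameters are
maximum pairwise distances between boundary voxels (per plane for the 2D
variants).

**Boruta.** Each iteration appends a column-wise independently permuted
copy of *every* feature and fits a random-forest impurity-importance
estimator; a feature scores a hit when its importance exceeds the
maximum shadow importance.  Hits are tested against Binomial(n, 1/2)
with two one-sided tests at level alpha/2, Bonferroni-corrected across
all features (alpha default 0.05, maxIter default 100, 300 trees).  The
full shadow set is retained every iteration: dropping decided features'
shadows would weaken the shadow noise floor as the run progresses and
inflate false confirmations on null data (we measured this directly
during development — with a shrinking shadow set, chance-correlated
noise features are confirmed at several times the nominal rate).
Tentative features are *not* included in the relevant set.

**Multi-subset selection.** Default 20 balanced subsets and a majority
(0.5) confirmation-frequency threshold; both are explicit configuration
values since the framework only requires "multiple" subsets.  If no
feature reaches the threshold, `relevantFeatures()` falls back to the
top-k (default 10) by frequency, with a warning — on very small desk
cohorts Boruta rightly confirms nothing, and the pipeline must still be
runnable end-to-end.

**Ensemble.** Balanced subsets take every minority sample plus an
equal-sized uniform draw of majority samples without replacement,
independently across subsets.  Default forest: 500 trees, sqrt(p) split
candidates, minimum node size 1 (so members can learn from small
balanced subsets); default boosting: 300 rounds, depth 4, learning rate
0.1.  The decision threshold for class metrics is fixed at 0.5;
threshold-free AUC is the primary metric.  All members are kept.

**DeLong.** Placement values use the midrank (half-credit) tie
convention; `var(AUC) = S10/n1 + S01/n0`; the 95% CI is the normal
approximation on the AUC scale truncated to [0, 1] (no logit transform).
Perfect separation gives SE = 0 and a degenerate point CI with a
warning.

## The synthetic cohort generator

`simulateVolumeCohort()` emulates the study inputs at desk scale: per
patient, a nested-ellipsoid tumor labeled with the FeTS scheme (NCR core
inside an ET shell inside an ED rim; radius ranges must nest) placed in
four sequence volumes built from smoothed Gaussian random fields.
Compartment mean offsets differ per sequence (e.g. ET bright on
postcontrast T1) but are identical for both classes; the IDH signal is
carried *only* by the correlation length of the tumor texture field
(default 3 voxels for mutated vs 1.2 for wild type).  This was a
deliberate choice: a mean-shift signal would make first-order features
sufficient and leave the texture machinery untested, whereas a
correlation-length signal exercises exactly the pipeline's hard parts.
The default mutated fraction is 0.27, the cohort prevalence the
framework was designed around.

What the generator does **not** emulate: scanner physics, bias fields,
motion, partial-volume effects, multi-site intensity heterogeneity,
infiltrative (non-ellipsoidal) tumor geometry, or any real biological
coupling between texture and genotype.  Passing tests on these fixtures
therefore demonstrates that the algorithms are implemented correctly and
behave as designed under controlled conditions — not that the pipeline
reaches any particular accuracy on clinical data.  Clinical-grade
performance estimates require multi-site MRI cohorts and are out of
scope for this package's shipped checks.

`simulateTabularCohort()` generates the tabular analogue for
selection/ensemble simulations: standard-normal noise features, a chosen
number of informative features with a class-conditional mean shift, and
a configurable majority:minority imbalance.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script sizes were chosen as the smallest
that still measure each property stably: feature-inventory conformance
on one 40-cubed-voxel study; texture-matrix oracle equivalence on 100
random arrays up to 6 cubed; Boruta null control over 50 runs at
n = 100, p = 20 and recovery at n = 300, p = 100, 5 informative
features, 1.5-SD shift, 10 subsets; bias reduction over 50 paired
replicates at 1:3 imbalance (n = 200 train, 600 test); DeLong against a
10,000-replicate bootstrap at n = 200; and the end-to-end pipeline on a
20-patient, 64-cubed cohort run twice to verify byte-identical
artifacts.  The pipeline configuration used by `runPipeline()` scales
the selection and training sizes down accordingly
(`defaultRunConfig()`); the module-level defaults (20 subsets, 100
iterations, 500 trees) are the ones intended for real cohorts.

## Known limitations

* The 2D slice-wise wavelet transform assumes the axial axis is the
  third array dimension.
* Feature values are not harmonized across scanners or sites; no
  intensity normalization is applied inside the extractor (a z-score
  option exists upstream of discretization in the configuration).
* Boruta is run independently per balanced subset; confirmation
  frequencies are not corrected for the overlap between subsets (all
  subsets share every minority sample).
* `Maximum2DDiameter*` features use boundary voxel centers, not mesh
  vertices, which can differ from mesh-based definitions by up to one
  voxel.
* With WT-only segmentations the NONENH ROI is unavailable; its columns
  are absent rather than imputed, and downstream selection on such
  cohorts must use the WT pool.
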