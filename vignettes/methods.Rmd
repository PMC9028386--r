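---
title: "Methods: dual-modality lesion radiomics with stability screening and repeated LASSO cross-validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-modality lesion radiomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`psmarad` analyses lesion-level radiomics from two quantitative
imaging modalities — [68Ga]Ga-PSMA-11 PET uptake (SUVbw, g/mL) and MRI
apparent diffusion coefficient maps (ADC, 10⁻⁶ mm²/s) — against a
binary histology endpoint, ISUP grade group 1 versus 2 and above. This
vignette is the package's own account of the statistical and numerical
choices; nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The analysis model

A lesion is a binary contour (mask) on a scalar volume. The analysis
assumes:

* intensities are quantitative and comparable across patients within a
  modality (SUVbw and ADC are, by construction);
* the endpoint is lesion-level: every contoured lesion carries its own
  histology-derived grade, and lesions without histological
  correspondence are imaging false positives to be discarded;
* contouring is the dominant nuisance source: features must be robust
  to millimetre-scale contour variation before they are allowed into a
  predictive model.

### Geometry and resampling

All geometry is done in physical millimetre space; voxel centres sit
at `origin + (index - 0.5) * spacing`. Both modalities are resampled
once, before any other processing, to a common 1 mm isotropic grid:
intensities trilinearly, masks by nearest neighbour (so masks stay
strictly binary and no intensity ringing is introduced). The output
grid covers the same physical extent rounded to the nearest whole
voxel. PET and MRI are assumed to share a frame (the synthetic
generator constructs them co-registered; registration of real data is
out of scope).

### Contour perturbation

Each mask yields four variants: a 1 mm contraction, the original, and
1 and 2 mm expansions. Expansion by `d` mm admits every voxel centre
within Euclidean distance `d` of the original mask; contraction keeps
voxel centres farther than `d` from the background. On the grid this
is exactly dilation/erosion with the discrete Euclidean ball —
implemented that way, and verified voxel-for-voxel against brute-force
distance evaluation in the tests. A 2 mm contraction is deliberately
not offered: on small lesions it routinely empties the mask. A 1 mm
contraction that empties a mask is flagged degenerate and that lesion
is dropped listwise from the affected feature's stability table.

### The feature battery

`feature_registry()` fixes 75 namespaced features; `extract_all()`
always emits exactly this set, with explicit `NA` for anything
undefined on the given input (never silent omission, never NaN
propagation). Downstream stages must handle the marker: the stability
stage drops a feature if more than 20 % of lesions are missing; the
modeling stage imputes remaining missingness with training-set
medians.

* **First order** (`stat.`): population moments (mean, variance,
  skewness, excess kurtosis), order statistics and type-7 percentiles,
  energy/RMS/mean absolute deviation, plus discretised-histogram
  entropy (log2), uniformity, and the 90th percentile of the
  discretised grey levels. Skewness and kurtosis are missing on a
  zero-variance region of interest.
* **Intensity-volume histogram** (`ivh.`): `v10`/`v90` are the volume
  fractions at or above 10 %/90 % of the ROI maximum intensity (the
  dose-volume-histogram convention — chosen because SUV and ADC are
  non-negative ratio scales where "fraction of maximum" is meaningful;
  note this differs from the IBSI min–max fractional-intensity
  variant); `i10`/`i90` are the intensities reached by the hottest
  10 %/90 % of the volume; both differences are included. A constant
  region gives all volume fractions 1 and zero differences.
* **Morphology** (`morph.`): voxel-counting volume; surface area by
  the coarea estimator — the binary mask is smoothed with a narrow
  Gaussian (sigma 1.5 mm) and the gradient magnitude integrated. This
  tracks the true boundary area of smooth blobs to about 1 % (raw
  voxel-face counting overestimates a sphere by ~50 %) but rounds
  sharp corners, so cube-like shapes are underestimated and the
  sphericity of a digital ball can slightly exceed 1. Elongation and
  flatness come from the eigenvalues of the voxel-coordinate
  covariance (missing below 4 voxels); inverse elongation is the
  reciprocal of elongation; area/volume density use the axis-aligned
  bounding box.
* **Texture** (`glcm.`, `glrlm.`, `glszm.`, `gldzm.`): computed on
  32-bin min–max quantisation within the ROI
  (`level = min(floor(32·(x−min)/(max−min)) + 1, 32)`; constant ROI →
  level 1). GLCM (symmetrised) and GLRLM are computed per direction
  over the 13 unique 3D unit offsets and averaged, skipping directions
  with no pairs/runs ("averaged" aggregation; a merged mode is not
  offered). GLSZM zones are 26-connected equal-level components;
  GLDZM distances are city-block distances to the ROI border (border
  voxel = 1, image edge counts as border). Correlation-type GLCM
  features are missing on a single-level ROI. Both information
  correlation variants are provided as separate keys. All four matrix
  constructions are tested for exact equality against brute-force
  enumeration on micro-fixtures.

### Stability screening

Feature robustness across the four contour variants is scored with the
two-way, absolute-agreement, single-measurement intraclass
correlation, ICC(A,1): with lesions as rows, variants as a fixed
crossed factor,

```
ICC = (MS_R − MS_E) / (MS_R + (k−1) MS_E + (k/n)(MS_C − MS_E)).
```

Absolute agreement is the right flavour here because a systematic
offset between contour variants is a real instability, not a
harmless recalibration — the tests verify that shifting one variant by
a constant strictly lowers the ICC. All-identical tables have ICC 1 by
convention; fewer than 3 usable lesions gives a missing ICC. The
threshold is strict: a feature survives iff ICC > 0.6 exactly (0.6
itself fails). One ICC is computed jointly over all four variants, not
pairwise against the original contour.

### Pairing

For lesions visible on both modalities the per-modality contours are
resolved into one analysis mask per modality: if one contour is
contained in the other (up to 5 % of the inner mask's voxels as
discretisation slack), the inner contour is used on both modalities;
else if the overlap exceeds 80 % of the *smaller* lesion's volume —
this denominator makes containment the continuous limit (fraction → 1)
of partial overlap — the voxel intersection is used; otherwise the
lesions are not associated. Matching is one-to-one, greedy by
descending overlap fraction with lexicographic tie-breaks, so a single
large MRI lesion facing several PET foci yields exactly one pair.

### Modeling

Five logistic models (PET lesions / MRI lesions / paired lesions with
PET, MRI, or both feature sets; combined features carry `PET.`/`ADC.`
prefixes) are each evaluated by 30 repetitions of: stratified 2/3–1/3
train/test split (train size `round(2n/3)`, largest-remainder
allocation across classes, both classes forced into both partitions);
training-set standardisation and median imputation (test data
transformed with training statistics — no leakage); LASSO-logistic fit
over 100 log-spaced penalties from the smallest all-zero penalty down
four decades, the penalty chosen by minimum stratified 3-fold CV
binomial deviance (not the 1-SE rule); unpenalised intercept;
intercept-only outcomes allowed (their constant scores give AUC 0.5
under the tie convention). AUC is the Mann–Whitney statistic with ties
counted one half, identical to the trapezoidal area under the
empirical ROC (verified to 1e-12 in the tests). Reported per model:
per-iteration train/test AUCs, their means over all 30 iterations
(including degenerate ones), the train/test pair of the best iteration
— defined as maximal test AUC, ties broken by train AUC then iteration
index, a reporting convention that is optimistically biased and should
be read as such — and per-feature selection frequencies.

Splits are drawn at the lesion level, so lesions of one patient can
straddle train and test; this mirrors the lesion-level endpoint but
can leak patient-level effects, which is a known caveat of the design
rather than of the implementation.

## The synthetic study

`cohort_config()` defaults define the simulated study the package is
validated on: 28 patients with 1–4 ellipsoidal lesions each (radius
3.5–7 mm) in a 60 mm field of view; PET native spacing 2.5/2.5/4 mm,
MRI-ADC 2.5/2.5/3 mm. Backgrounds and lesion interiors are Gaussian
random fields (white noise smoothed with a Gaussian kernel of the
configured correlation length, affinely rescaled to the target
mean/SD). Grade structure: 40 % of true lesions are ISUP 1; ISUP 2+
lesions have higher SUV, lower ADC (the configured effect size is the
standardised mean difference of lesion mean intensity, default 1.5,
split symmetrically about the grand mean) and rougher texture
(correlation length 1.5 mm vs 3 mm). Per modality, contours are the
true ellipsoid jittered in centre (1 mm SD between modalities) and
radii (0.6 mm SD), with MRI contours additionally enlarged by 0.8 mm —
emulating the tendency of ADC contours to run large and making full
containment a realisable pairing regime. 90 % of true lesions are
PET-visible (invisible ones get sub-threshold uptake, mean SUV 2),
75 % MRI-visible; 18 % of contoured lesions have no histology match
and are discarded at the label join. ADC values are clipped at 0.
These rates were chosen once so that a default run lands near the
intended study scale (≈49 PET / ≈37 MRI true-positive lesions, ≈31
paired) and were not tuned afterwards.

What the phantoms deliberately do **not** emulate: anatomical context
(no organs, no heterogeneous background structures), acquisition
physics (no PET partial-volume blur beyond grid resolution, no noise
correlation between modalities, no ADC fitting artefacts), irregular
lesion shapes, or inter-observer contouring behaviour beyond isotropic
jitter. Passing tests on these phantoms therefore demonstrate the
*correctness of the computations* and the *sanity of the statistical
machinery* (signal is recovered when planted, chance level is
recovered under label permutation), not clinical performance on real
images — on the phantoms the class signal is cleaner than any real
cohort, and the resulting AUCs are correspondingly optimistic.

## Numerical choices and degenerate inputs

* Determinism: every stochastic stage derives its seed from the master
  seed; identical configuration + seed reproduces byte-identical
  outputs (hash-manifested per run).
* Problem sizes: the test suite validates texture oracles on ≤5³
  fixtures (exact equality), geometry on ≤32³ grids, ICC against ANOVA
  on hundreds of random tables (1e-10), modeling properties on n = 60
  feature tables with 30 CV repetitions and 10 cohort replicates, and
  the complete default study (28 patients) end to end — about two
  minutes in total on one core.
* Empty/degenerate inputs error loudly (empty mask, single-class
  labels, missing ground-truth rows) or carry explicit flags
  (degenerate contraction variants, missing features); model
  configurations with an empty or single-class lesion subset are
  skipped with a logged reason, never silently absent.
* Ties: AUC counts ties one half; pairing ties on overlap fraction are
  broken by lesion id; the best CV iteration breaks test-AUC ties by
  train AUC then index.

## Known limitations

* The coarea surface-area estimator underestimates sharp-cornered
  shapes (a cube's area by ~20 %); for the ellipsoidal lesions the
  pipeline targets it is accurate to ~1 %.
* The 218-feature census of any particular vendor tool is not
  reproduced; the battery is the documented 75-feature registry
  containing the families and named features the analysis requires.
  Vendor-ambiguous names ("inverse elongation", "area density",
  "information correlation") are implemented under documented
  conventions (reciprocal elongation; AABB density; both IBSI
  information-correlation variants).
* Lesion-level splitting, the best-iteration reporting convention, and
  30 repetitions are faithful to the analysis design the package
  implements, including its statistical weaknesses on small cohorts
  (high split-to-split variance, optimistic best-iteration AUCs).
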