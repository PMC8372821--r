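---
title: "Radiomic laterality analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic laterality analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In temporal lobe epilepsy (TLE), knowing which hemisphere harbors the
epileptogenic focus drives presurgical planning. Hippocampal sclerosis is
the classic MRI-visible lesion, but a substantial fraction of TLE is
"MRI-negative": the hippocampus looks normal. The working hypothesis behind
this package is that subtle textural abnormality — voxel-level
heterogeneity rather than gross atrophy — is present on FLAIR images, both
in the hippocampus and in the surrounding (extrahippocampal) temporal
cortex, and that a penalized classifier trained on high-dimensional
radiomic descriptors of those regions can score each hemisphere and call
the affected side.

`radlat` implements that analysis end to end: image ingestion and
isotropic resampling, white-stripe intensity normalization, four-ROI
assembly from an anatomical parcellation, extraction of a 1,618-dimensional
radiomic feature vector per ROI, univariate filtering with FDR control,
elastic-net penalized logistic modelling with cross-validated
hyperparameters, and ROC-based evaluation. A seedable phantom simulator
generates cohorts with the statistical structure the analysis assumes, so
every stage runs and is testable without clinical data.

## Pipeline and model

### Preprocessing

All images are resampled to a 1 mm isotropic grid (trilinear for
intensities, nearest-neighbour for label maps; the output extent is
`ceil(physical extent / target)` so tissue is never cropped). FLAIR
intensities are in arbitrary units, so each volume is standardized by the
white-stripe method: a kernel density estimate of the in-brain intensity
distribution locates the normal-appearing-white-matter mode, the "stripe"
is the band between the `F(mode) ± tau` empirical quantiles (`tau = 0.05`,
the method's published default), and the volume is mapped to
`(I - mu_ws) / sigma_ws` using the stripe mean and SD. The estimator is
affine-equivariant, so the normalized image does not depend on scanner
scaling. The default is a single-contrast FLAIR stripe with the
largest-mode rule, because only FLAIR feeds the feature extraction; a
two-contrast hybrid entry point (`estimate_stripe_hybrid()`, stripe =
intersection of the two stripe masks) is provided for T1+FLAIR use.
Normalization is applied after resampling; with a brain mask taken as the
union of all parcellation labels when no dedicated mask exists.

### The 1,618-feature vector

Per ROI the default extraction emits exactly 1,618 named features:

* 17 first-order statistics of the raw intensities (entropy and uniformity
  over a 32-level histogram);
* 162 texture features: 23 gray-level co-occurrence (GLCM) features at
  distances 1, 2, 3 voxels and 12 gray-level run-length (GLRLM) features,
  each under two aggregations over the 13 unique 3D directions
  (direction-averaged, and merged-matrix);
* 7 shape descriptors of the binary mask (volume, face-count surface area
  and derived ratios, maximum 3D diameter) — geometric quantities, so they
  are computed once, on the original grid only;
* 8 × 179 = 1,432 wavelet features: the 17 first-order + 162 texture
  features re-extracted on each sub-band of a single-level undecimated
  (stationary) 3D wavelet transform.

The decomposition 17 + 162 + 7 + 1,432 = 1,618 fixes the feature-name
schema `<image>_<family>[_<dist>][_<agg>]_<feature>`, which model
artifacts reference by name so extraction-order changes cannot silently
corrupt predictions.

Texture matrices are built on gray levels quantized to a fixed number of
bins (32) over the ROI's own intensity range; fixed-bin-number is the
appropriate choice for z-scaled (white-striped) inputs, and the count is
config-exposed (`disc_config()`). Feature formulas follow the IBSI
reference definitions. Degenerate inputs never produce NaN: a constant ROI
yields entropy 0, uniformity 1, skewness/kurtosis 0, and a GLCM with no
valid pairs yields defined point-mass fallbacks (0 for entropy/contrast
types, 1 for energy types).

The undecimated transform was chosen over the decimated one so that the
ROI mask applies unchanged to every sub-band (no ill-defined mask
halving); the family is coiflet-1 with periodic boundary handling — a
common radiomics default — and both are config-exposed. Sub-bands are
named by axis order (z, y, x). Internally the transform runs on the ROI
bounding box padded by the filter support, which leaves in-mask sub-band
values identical while keeping per-ROI cost proportional to ROI size.

### Contrast designs and feature selection

Two designs mirror the clinical question. The hippocampal design (H+)
contrasts affected-side hippocampal ROI rows of patients against the
pooled unaffected-side rows of patients and one hemisphere per control;
the temporal design (H−) does the same with the extrahippocampal temporal
ROI. Controls have no affected side, so the contributing hemisphere is
drawn uniformly per control under a fixed, logged seed. Pairing between a
patient's two hemispheres is deliberately ignored (independent two-sample
pooled t-tests, matching the 36-vs-86 clinical design this emulates); this
is a known statistical simplification.

Each feature is tested with a pooled-variance two-sided t-test and the
p-values are adjusted by Benjamini–Hochberg; features pass at `q < 0.05`.
Features surviving the filter are standardized with training-set
statistics (zero-variance columns dropped and recorded) and passed to the
elastic-net logistic model

\[
\min_{\beta_0, \beta}\; -\tfrac1n \sum_i \big[y_i \log p_i + (1-y_i)\log(1-p_i)\big]
 + \lambda\big[(1-\alpha)\lVert\beta\rVert_2^2/2 + \alpha\lVert\beta\rVert_1\big],
\qquad p_i = \mathrm{logistic}(\beta_0 + \beta^\top z_i),
\]

with `alpha` searched over `0, 0.05, …, 1` and, per alpha, `lambda` over a
100-point log-spaced path spanning four decades below the smallest
all-zero lambda. Hyperparameters minimize the 10-fold stratified
cross-validated mean squared error between predicted probability and 0/1
label (probability-scale MSE, not deviance, matching the protocol this
reimplements). Selection uses the one-standard-error rule by default:
among all grid points whose mean CV MSE lies within one standard error of
the minimum, the most parsimonious one wins — the most penalized point of
its own lambda path first (raw lambda values are not comparable across
alpha, because the path entry point scales with 1/alpha), then the more
lasso-like alpha. The raw minimizer is available via
`enet_config(selection_rule = "min")`, but at laterality-study sample
sizes (tens of rows, hundreds-to-thousands of candidate features) the raw
minimum chases cross-validation jitter: on pure-noise cohorts it
routinely returns densely parameterized models whose held-out AUC swings
far from 0.5, whereas the 1-SE band returns the intercept-only model the
data support. This choice is what keeps the pipeline null-calibrated. The filter runs once on the full training set rather than
nested inside the folds — again mirroring the two-step protocol — which
is optimistically biased for internal error estimates; held-out evaluation
on independent cohorts is therefore the meaningful measure. When fewer
than two features survive the filter (the expected situation under a null
cohort), the filter is bypassed and the penalty alone performs selection,
so training always completes and may legitimately return an
intercept-only model.

### Evaluation

`roc_auc()` is the Mann–Whitney pair statistic (ties one half);
`youden_threshold()` scans midpoints between adjacent distinct scores and
returns the lowest threshold maximizing sensitivity + specificity
(positive when score ≥ threshold); `auc_ci()` is a stratified percentile
bootstrap (2,000 replicates by default, seed-deterministic; resampling
positives and negatives separately guarantees both classes in every
replicate). Per-patient laterality is the argmax of the two hemisphere
scores, with exact ties reported as indeterminate. Validation AUC is
computed over side-level samples (affected side positive), mirroring the
training contrast.

## The phantom simulator

`make_cohort(phantom_spec())` generates FLAIR-like cohorts: an ellipsoidal
"brain" at base intensity 100 a.u. textured by a Gaussian random field
(smoothed white noise, kernel SD `l_null = 2` voxels, field SD 6) plus
white voxel noise (SD 8). Hippocampi are mirrored ellipsoids; the
extrahippocampal temporal regions are mirrored ellipsoidal shells around
them; labels use the parcellation IDs of the shipped grouping table so the
phantoms flow through exactly the clinical code path. Patients receive, in
the ROIs of one hemisphere (drawn with equal probability), an intensity
shift of `delta` total-noise SDs and a texture field with correlation
length `l_ratio × l_null`. Both effect fields are smoothings of the *same*
white-noise realization, so setting `delta = 0, l_ratio = 1` produces a
patient image voxel-identical to the control construction — the null
cohort is exchangeable by construction, not merely approximately so.
Cohort sizes default to 36 patients + 50 controls, matching the clinical
training cohort the simulator emulates; the default grid is 64×64×48 at
1 mm so a full-cohort extraction runs in minutes.

What the phantom does *not* emulate: anatomy (no cortical folding, no
partial-volume tissue mixtures), scanner physics (no bias fields, no Rician
noise), registration error, or between-subject anatomical variability.
Passing tests therefore demonstrate that the pipeline recovers planted
intensity/texture asymmetries of the stated effect size under clean
conditions — a correctness statement about the software and the statistics,
not a claim about clinical sensitivity.

## Numerical choices and edge cases

* Trilinear interpolation clamps at volume edges; nearest-neighbour
  resampling preserves the label value set exactly.
* The stripe estimator refuses constant images and empty brain masks with
  named errors; stripe SD must be positive.
* `student_t()` defines p = 1 for identical constant groups and p = 0 for
  different constant groups (flagged), so feature screening never emits NaN.
* The lambda path uses the coordinate-descent entry point
  `max |X'(y - ybar)| / (n · max(alpha, 0.001))`, keeping the ridge end of
  the alpha grid on a finite path.
* Youden ties return the lowest maximizing threshold; AUC ties count 1/2.
* Feature extraction asserts that all 1,618 values are finite and names
  unique before returning.

## Simulation sizes used by the test suite

The acceptance checks run the full pipeline at sizes chosen to exercise
every stage on a single CPU in minutes: per seed, a training cohort of
10 patients + 10 controls and a held-out cohort of 8 + 8 on the default
64×64×48 grid, hippocampal design, with 10 seeds per condition
(strong-effect `delta = 2, l_ratio = 3`; null `delta = 0, l_ratio = 1`).
The planted-feature recovery study uses 200 samples × 50 features with 5
active coefficients of 1.5 across 25 seeded replicates, and the FDR null
study uses 200 replicates of 100 exchangeable features (12 vs 15 samples).
These sizes are the package's own choices for routine verification; the
simulator scales to larger cohorts by changing `phantom_spec()`.

## Known limitations

* The univariate filter is not nested within cross-validation; internal CV
  error is optimistic. Held-out cohorts are the honest benchmark.
* Within-patient pairing is ignored by the two-sample t filter.
* The 17-member first-order set, the 23+12 texture decomposition and the
  32-bin quantization are the standard community choices for this feature
  budget; other radiomics software may differ in individual formula
  conventions (e.g. surface area by mesh rather than face counting, which
  systematically changes sphericity-type values).
* Probabilities from the penalized model are not calibrated; only the
  ranking (AUC, laterality argmax) should be interpreted.
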