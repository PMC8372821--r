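# radlat — radiomic laterality analysis for temporal lobe epilepsy

`radlat` is an R package for lateralizing temporal lobe epilepsy (TLE)
from FLAIR MR volumes and an anatomical parcellation. Up to 30% of TLE is
"MRI-negative" — no visible hippocampal sclerosis — yet subtle textural
abnormality may still mark the affected hemisphere, both in the
hippocampus and in the surrounding extrahippocampal temporal cortex. The
package turns that idea into a tested, reproducible pipeline:

1. **Image ingestion** (NIfTI), resampling to a 1 mm isotropic grid;
2. **White-stripe intensity normalization** — anchor normal-appearing
   white matter to zero mean / unit spread via the density mode of the
   in-brain intensity distribution;
3. **ROI assembly** — collapse parcellation labels into four regions:
   left/right hippocampus, left/right extrahippocampal temporal lobe
   (a Desikan/Killiany grouping table ships as the default);
4. **Radiomic extraction** — exactly **1,618 named features per ROI**:
   17 first-order + 162 texture (GLCM at distances 1–3 and GLRLM over the
   13 unique 3D directions, direction-averaged and merged) + 7 shape +
   8 × 179 features on the sub-bands of an undecimated 3D wavelet
   transform (coiflet-1);
5. **Model fitting** — pooled t-tests with Benjamini–Hochberg FDR
   filtering, then elastic-net penalized logistic regression

   min over (β₀, β) of  −(1/n) Σᵢ [yᵢ log pᵢ + (1−yᵢ) log(1−pᵢ)]
   + λ[(1−α)‖β‖²/2 + α‖β‖₁],  pᵢ = logistic(β₀ + βᵀzᵢ)

   with (α, λ) tuned by stratified 10-fold cross-validation on
   probability-scale MSE. The fitted linear score is the laterality score;
6. **Evaluation** — Mann–Whitney AUC, Youden-optimal thresholds,
   stratified bootstrap confidence intervals, per-patient laterality calls
   (argmax of the two hemisphere scores).

Because clinical images cannot ship with the package, a seedable phantom
simulator (`phantom_spec()` / `make_cohort()`) generates FLAIR-like
cohorts with mirrored hippocampal/temporal ROIs in which the affected
side carries an intensity shift and altered texture-field correlation
length — the statistical structure the analysis assumes — so every stage
runs and is testable offline.

## Worked example

Train on a strong-effect phantom cohort and evaluate on an independent
held-out cohort:

```r
library(radlat)

train <- make_cohort(phantom_spec(n_patients = 10, n_controls = 10, seed = 11))
tab   <- extract_cohort(train, rois = "hippocampal")

fit <- laterality_model(tab, design = "hippocampal", seed = 11)
print(fit)
#> Radiomic laterality model (hippocampal design)
#>   n = 30 samples, 296 candidate features (296 passed the BH q<0.05 filter)
#>   elastic net: alpha = 1, lambda = 0.03446, 8 nonzero coefficients
#>   cross-validated MSE = 0.0409

heldout <- make_cohort(phantom_spec(n_patients = 8, n_controls = 8, seed = 111))
tab2    <- extract_cohort(heldout, rois = "hippocampal")
print(evaluate_model(fit, tab2, n_boot = 500, seed = 11))
#> AUC 1.000 (95% CI 1.000-1.000)
#> Youden threshold 0.329: sensitivity 1.000, specificity 1.000
#> Laterality calls: 8/8 correct
```

Reading the output: 296 of the 1,618 features survived the FDR filter on
this contrast (affected hippocampi of 10 patients vs the pooled 20
unaffected-patient and control hippocampi); cross-validation under the
one-standard-error rule picked a pure LASSO penalty (α = 1) keeping just
8 features; on the untouched held-out cohort every (positive, negative)
score pair is ordered correctly (AUC 1.0) and the side with the larger
score is the true affected side in all 8 patients. With `delta = 0, l_ratio = 1` (a null cohort, no planted
effect) the same pipeline returns an intercept-only model and a held-out
AUC of 0.5.

A command-line interface wrapping the same functions ships in
`inst/cli/radlat.R` with subcommands `simulate`, `extract`, `train`,
`evaluate` operating on NIfTI cohorts, CSV feature tables and JSON model
artifacts.

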