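# pvscade

Cascaded enhancement and counting of enlarged perivascular spaces (ePVS) in
the basal ganglia on T2-weighted MRI.

## What problem this solves

Enlarged perivascular spaces are small CSF-bright foci on T2-weighted MRI
whose burden in the basal ganglia is an imaging marker of cerebral
small-vessel disease. Clinically they are rated on the Potter scale — an
ordinal grade driven by the ePVS count in the region of interest

| grade | 0 | 1 | 2 | 3 | 4 |
|---|---|---|---|---|---|
| count | 0 | 1–10 | 11–20 | 21–40 | > 40 |

on three contiguous axial slices per hemisphere (six "part" images per
subject; the subject grade is the maximum of the six). Manual counting is
slow and rater-dependent. `pvscade` implements and evaluates a two-stage
automated pipeline for researchers working on ePVS quantification:

1. **ePVS enhancement** — a U-Net image-to-image regressor trained with MSE
   toward the target `minmax(image + mask)`, i.e. the normalized T2 part
   with the binary ePVS mask added and renormalized to [0, 1]. The learned
   map selectively pushes ePVS pixels to the top of the intensity range.
2. **ePVS quantification** — a five-layer CNN (filters 64, 64, 128, 128,
   256; batch norm + ReLU; global average pooling; one linear unit) trained
   with MAE on counts normalized by the cohort maximum (48), applied to the
   enhanced images; predictions are clipped to [0, 1] and rescaled.

Evaluation follows the clinical protocol: contrast-to-noise ratio
`CNR = |mu_signal1 − mu_signal2| / sigma_noise` for enhancement quality
(against white top-hat, CLAHE and Laplacian-sharpening baselines), count
MAE/MSE, Potter-grade accuracy at image and subject level, ICC(2,1) with
95% CI, all under subject-level 4-fold cross-validation.

Both networks are implemented natively in R/RcppArmadillo (im2col + GEMM
convolutions, batch norm, Adam, geometric augmentation) — no external
deep-learning framework is required — and a seeded synthetic phantom module
(grade-skewed bright puncta on textured tissue, with exact masks and
counts) makes the whole cascade trainable and testable without patient
data.

## Worked example

Generate a 40-subject phantom cohort, preprocess it to 80×96 unit-range
parts, and cross-validate the cascade against the no-enhancement pipeline
(the `desk` preset is sized for a single CPU; `preset = "paper"` holds the
full published recipe):

```r
library(pvscade)

parts <- preprocess_cohort(generate_cohort(40, phantom_params(), seed = 7))
cfg   <- train_config("desk")

cv_dl   <- run_cross_validation(parts, "dl",   cfg, k = 4, seed = 7)
cv_none <- run_cross_validation(parts, "none", cfg, k = 4, seed = 7)

as.data.frame(glance(cv_dl))
#>   method n_images      mae      mse image_accuracy subject_accuracy mean_cnr
#> 1     dl      240 2.282509 9.304508       80.83333               75 10.16814
#>   icc_image icc_subject
#> 1 0.8826656   0.7925532
as.data.frame(glance(cv_none))
#>   method n_images      mae      mse image_accuracy subject_accuracy mean_cnr
#> 1   none      240 3.226427 17.76577          68.75               65 3.865174
#>   icc_image icc_subject
#> 1 0.8171161   0.7026144
```

Reading: with learned enhancement the pooled cross-validated count error is
2.3 ePVS (vs 3.2 without enhancement, and 8.4 for predicting the cohort
mean), exact Potter-grade agreement is 81% at image level and 75% at
subject level, and the mean CNR of the enhanced test images is 10.2 —
versus 3.9 non-enhanced, 7.0 white top-hat, 6.8 Laplacian and 2.7 CLAHE on
the same parts. The orderings (learned enhancement best in CNR, cascade
lowest in MAE) mirror the published comparison; absolute values are
phantom-specific and not comparable to patient-data results.

`autoplot(cv_dl)` draws predicted-vs-true counts; `tidy()`/`glance()` give
per-fold and pooled metric tables; `write_report()` serializes a run to
JSON/CSV.

A command-line interface wraps the same pipeline
(`inst/cli/pvscade simulate | preprocess | enhance | train-enhancer |
train-quantifier | evaluate | run-cv`), each verb writing a `manifest.json`
with the resolved configuration and seed.

See `vignettes/pvscade-methods.Rmd` for the model, the phantom's stated
world, and all numerical design choices.

## Acceptance script

`scripts/acceptance.R` recomputes the package's structural acceptance
quantities from scratch — the Potter grades at bracket-boundary counts, the
part count of a preprocessed 76-subject synthetic cohort, and the 4-fold
subject split size — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
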