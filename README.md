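# radtex

Texture radiomics of masked brain-MRI tissue regions, built for two-class
questions of the form *"does the texture of this tissue tell the classes
apart?"* — the motivating case being detection of the presence or subtype of
ischaemic stroke from conventionally segmented tissues (normal-appearing
white matter, white matter hyperintensities, subcortical structures) on
structural MRI, where the stroke lesion itself is *not* analysed.

It is aimed at imaging researchers who have, per subject, one or more 3D
grey-level volumes (NIfTI) with co-registered binary ROI masks and a binary
label, and who want a tested, deterministic, leakage-safe pipeline from
voxels to cross-validated AUC.

## What it computes

**114 texture descriptors per masked volume.** Each 2D slice with enough
in-mask pixels contributes a full descriptor vector; the 3D value of each
descriptor is the median over slices. The families:

| Family | n  | Content |
|--------|----|---------|
| GLCM   | 13 | Haralick statistics of the grey-level co-occurrence matrix (Ng = 32, d = 1), features averaged over θ ∈ {0°, 45°, 90°, 135°}: energy, contrast, correlation, variance, homogeneity, sum average/variance/entropy, entropy, difference variance/entropy, FIMC, SIMC |
| GLRLM  | 11 | Run-length statistics (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE), averaged over the same four directions |
| LBP    | 40 | Rotation-invariant local binary patterns (P = 8, R = 1, raw intensities): the 36 canonical-pattern histogram bins plus median, variance, skewness, kurtosis of the code map |
| WSF    | 26 | Mean and SD of the original in-mask intensities and of the 12 subbands of a 3-level orthonormal Haar decomposition |
| WCF    | 24 | Six GLCM statistics (energy, contrast, correlation, homogeneity, entropy, variance) of each level-1 Haar subband |

An 8-bit LBP code is `LBP_{R,P} = Σ_p s(g_p − g_c) 2^p` with `s(x) = 1` iff
`x ≥ 0`; rotation invariance maps each code to the minimum over its circular
rotations, leaving exactly **36** canonical patterns.

**Screening.** Per-feature Mann-Whitney U tests (exact for small tie-free
samples, tie- and continuity-corrected normal approximation otherwise) with
Holm-Bonferroni step-down control of the family-wise error rate, tabulated
as significant-before / significant-after counts per (sequence, tissue).

**Classification.** 10×-repeated stratified 5-fold cross-validation of a
linear soft-margin SVM (C ∈ {2⁻³ … 2³}) and a 250-tree random forest
(mtry ∈ {2, 4, …, 12}); performance is the AUC averaged over the 50
iterations (mean ± SD), plus sensitivity/specificity/accuracy at the native
thresholds. Filter feature selection (Mann-Whitney p-value or maximal
information coefficient rankings) is fit **inside each training fold**, as
is standardization, so test folds never leak into the fit. Per-sample
consistency (proportion of test appearances classified correctly) and
bootstrapped Pearson correlations against covariates close the loop.

**Synthetic phantoms.** Because no patient data ships with the package, a
generator produces two-class cohorts of 3D volumes whose masked regions
differ in spatial texture — correlation length and local contrast of a
seeded Gaussian random field — at a controllable effect size, with blob,
shell, or scattered-cluster masks and degenerate cases (constant volumes,
one-voxel masks, empty slices) for the invalid-feature path.

## Worked example

```r
library(radtex)

spec <- phantom_spec(volume_shape = c(32, 32, 12), mask_kind = "blob",
                     mask_fraction = 0.15, effect_size = 1)
cohort <- generate_cohort(spec, n_per_class = 15, base_seed = 42)
cohort$volumes[[1]]
#> volume_with_mask S001 FLAIR NAWM : 32x32x12 voxels, 1844 in mask

features <- clean_table(extract_study_features(cohort, texture_config()))
features
#> feature_table: 30 subjects x 111 features; 15 positive labels

screen_table(features)
#> screen_result: 111 features, alpha = 0.05 , family = per_dataset
#>   sequence tissue before after
#> 1    FLAIR   NAWM     78    53

evaluate(features, model_grid(svm_C = c(0.5, 1, 2), rf_mtry = c(2, 6)),
         cv_plan(k = 5, R = 10, base_seed = 42))
#> cv_result: 5 configurations x 50 iterations ( 0 failed )
#>   best svm: hyper = 0.5, AUC = 1.000 (SD 0.000)
#>   best rf: hyper = 2, AUC = 1.000 (SD 0.000)
```

Reading: three of the 114 features were dropped by cleaning (invalid or
near-zero variance on this cohort); 78 of the remaining 111 separate the
classes at raw p < 0.05 and 53 survive Holm correction; with a strong
texture effect (`effect_size = 1`, smoothing scale doubled and local
contrast ×1.5 in class 1) both classifiers reach AUC 1.000 across all 50
cross-validation iterations. At `effect_size = 0` the same pipeline hovers
at chance.

The same chain runs from the command line, stage by stage, resumable from
serialized outputs:

```sh
Rscript -e 'radtex::run_cli()' simulate --config cfg.json
Rscript -e 'radtex::run_cli()' extract  --config cfg.json
Rscript -e 'radtex::run_cli()' evaluate --config cfg.json
```

## Documentation

The methods vignette (`vignettes/radtex-methods.Rmd`) documents the model
assumptions, every tunable parameter with its default and rationale, what
the phantom generator does and does not emulate, numerical conventions
(quantization ranges, entropy base, SD conventions, tie-breaks), and known
limitations.
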