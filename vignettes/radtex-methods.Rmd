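---
title: "radtex: methods, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radtex: methods, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtex)
```

# The analysis model

`radtex` implements a texture-radiomics analysis for masked 3D grey-level
volumes with binary subject labels. The chain is:

1. **Per-slice 2D texture extraction, median aggregation to 3D.** Each axial
   slice with at least `min_mask_pixels` in-mask pixels yields the full
   114-descriptor vector; the volume's value of each descriptor is the
   median over the slices where it is finite. The rationale for 2D-then-
   aggregate rather than true-3D texture matrices is slice thickness: when
   through-plane resolution is several times coarser than in-plane
   resolution, 26-neighbour 3D co-occurrence mixes anisotropic scales and
   is generally discouraged. True-3D matrices are deliberately out of
   scope.
2. **Cleaning.** Columns with any non-finite value (features that fail on
   small or degenerate regions) are removed, then zero- and
   near-zero-variance columns. No imputation, ever: a feature that cannot
   be computed for some subject is dropped for all.
3. **Univariate screening.** A two-sided Mann-Whitney U test per feature,
   with Holm-Bonferroni step-down control of the family-wise error rate.
   The screen is descriptive (which features separate the classes on their
   own); it does not gate the classifiers, because features useless alone
   can contribute in combination.
4. **Classifier evaluation.** Stratified 5-fold cross-validation repeated
   10 times (50 iterations), for a linear SVM over a cost grid and a
   random forest over an mtry grid. The headline statistic is the mean
   AUC over the 50 per-iteration AUCs, with its SD — not the AUC of pooled
   predictions. Optional filter feature selection (p-value or MIC
   ranking) is recomputed inside every training fold.

## Assumptions

* Masks are trusted inputs: co-registered, binary (anything nonzero is
  in-mask), and in voxel correspondence with their volume. Affines are
  checked for agreement and never resampled; a mismatch is an error.
* Labels are binary and per subject; cohorts need both classes, with at
  least `k` subjects per class for `k`-fold CV.
* Intensities are in arbitrary units. Nothing assumes a physical scale:
  GLCM/GLRLM quantize to relative bins, LBP uses only intensity order,
  wavelet features are linear in the input.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `Ng` | 32 | grey levels | co-occurrence bin count; 32 balances SNR and resolution for 8-bit-ish MRI |
| `d` | 1 | pixels | co-occurrence offset; 1 emphasises local structure |
| `directions` | 0°, 45°, 90°, 135° | — | per-direction features are averaged for rotation invariance |
| `lbp_P`, `lbp_R` | 8, 1 | neighbours, pixels | the original 3×3 LBP operator; fixed because the 36-bin canonical histogram is specific to 8 bits |
| `dwt_levels` | 3 | levels | Haar decomposition depth for WSF |
| `min_mask_pixels` | 16 | pixels | smallest slice that contributes; 16 guarantees a nondegenerate 3×3 LBP neighbourhood and co-occurring pairs |
| `range_policy` | `"volume"` | — | quantization reference range (below) |
| `nzv_freq_ratio`, `nzv_unique_pct` | 19, 10 | —, % | the common caret-style near-zero-variance rule |
| `svm_C` | 2⁻³ … 2³ | — | soft-margin cost grid |
| `rf_mtry` | 2, 4, …, 12 | features | variables tried per split |
| `rf_ntree` | 250 | trees | diminishing returns beyond this at n ≈ 100 |
| `k`, `R` | 5, 10 | folds, repeats | 50 models per hyperparameter |
| `mic_grid_exponent` | 0.6 | — | MIC grid-area bound B(n) = n^0.6 |

# Numerical conventions

These are the choices a reimplementation would need to reproduce our
numbers exactly; none of them is forced by the mathematics.

* **Quantization reference range** (`range_policy = "volume"`): uniform
  bins over the min–max of in-mask voxels of the *whole volume*, so all
  slices share one grey scale and the slice-median compares like with
  like. Per-slice ranges are available (`"slice"`) but make the aggregate
  sensitive to slice-wise outliers. The top of the range maps to level
  `Ng`; a constant region maps wholly to level 1.
* **GLCM:** only ordered pixel pairs with both members in-mask count; each
  directional matrix is symmetrised by adding its transpose before
  normalization (0° ≡ 180°). The 13 statistics are averaged over
  directions — features averaged, not matrices — skipping non-finite
  directions; all-non-finite stays `NA`. Entropies use **log base 2**.
  Sum variance is computed about the sum average (not the sum entropy,
  a known erratum in the original tables).
* **GLRLM:** runs are maximal same-level in-mask segments; mask gaps break
  runs. The run-percentage denominator is the in-mask pixel count (the
  common convention; "number of possible runs" is ambiguous in the
  original definition).
* **LBP:** raw intensities (no quantization), s(0) = 1, canonical code =
  minimum over the 8 circular rotations; the 36 canonical codes sorted
  ascending define bins `LBP_1..LBP_36`. The histogram is normalized to
  relative frequencies because mask sizes differ by orders of magnitude
  across subjects. Statistics of the code map: median; sample variance
  (n−1); moment-based skewness; non-excess kurtosis. A pixel is valid only
  if its full 3×3 neighbourhood is in-mask.
* **Wavelets:** orthonormal Haar; the input is the mask bounding-box crop
  with out-of-mask pixels set to the in-mask mean (zero-fill would inject
  a spurious edge). Odd dimensions are edge-replicated to even at each
  level. WSF uses sample SDs. For WCF each level-1 subband is quantized to
  `Ng` bins over its own min–max (signed coefficients have no shared
  reference range) and processed exactly as a GLCM slice.
* **Mann-Whitney U:** U counts pairs with x > y plus half-ties; exact
  p-values (null Wilcoxon distribution) when combined n ≤ 12 with no
  ties, otherwise the normal approximation with tie and continuity
  corrections. The cutoff is configurable; 12 keeps the exact path cheap.
* **Holm:** step-down thresholds α/(m−k+1); adjusted p = running max of
  (m−k+1)·p, capped at 1. The correction family defaults to the features
  of each (sequence, tissue) dataset; a pooled family over all columns is
  available — with several datasets the two are genuinely different
  analyses, so both are exposed rather than guessed.
* **MIC:** equipartition of one axis, dynamic-programming optimisation of
  the other over clump boundaries (superclump coarsening bounds the DP at
  15·nx cells), both orientations, grid area ≤ n^0.6, normalization by
  log2(min(nx, ny)). Ranking ties break by feature name.
* **Classifier scores:** SVM scores are signed distances to the hyperplane
  (bias absorbed as an augmented constant feature; dual coordinate descent
  on the L1-hinge dual); RF scores are the fraction of 250 gini CART trees
  voting positive, trees grown to purity on bootstrap resamples.
  Sensitivity/specificity/accuracy use the native thresholds (0 and 0.5);
  no threshold tuning.
* **Seeds:** every stochastic component (phantom fields, fold shuffles,
  tree RNG, bootstrap) derives from one run seed through `spawn_seed()`,
  a fixed integer mixing function; results are bit-reproducible.
* **Degenerate inputs:** constant regions, one-voxel masks and empty
  slices produce `NA` features with `validity = FALSE`, not errors; a
  training fold that loses a class flags and excludes the iteration; a
  feature constant within a training fold is excluded for that fold only.

# The phantom generator

The synthetic cohorts exist so that every downstream stage is testable
with no data download. Each subject is a 3D Gaussian random field:
`base + contrast · smooth(noise, scale) + noise_sd · white noise`, clipped
to non-negative. Class 1 differs from class 0 by texture only — smoothing
scale ×(1 + effect_size) and contrast ×(1 + 0.5·effect_size) — with the
base intensity shared, so first-order mean carries no class signal; this
mirrors the premise that texture, not brightness, encodes the condition.
Masks are thresholded smoothed fields: a central irregular blob, a
spherical shell, or scattered small clusters emulating white-matter-
hyperintensity lesion maps (the small-region failure path). A per-subject
log-normal jitter (SD 0.05) on the smoothing scale provides within-class
heterogeneity, and one covariate is generated with a configurable true
correlation to that subject-level texture parameter, the rest independent
noise.

What the phantoms **do not** emulate: MRI physics (bias fields, partial
volume, Rician noise), acquisition protocol differences, registration
error, or anatomically shaped tissue. A green phantom test therefore
establishes that the *pipeline* recovers texture differences it is pointed
at — deterministically, without leakage, with calibrated error control —
not that any particular clinical discrimination is achievable. The
quantitative texture parameters are free choices exposed in configuration,
not estimates of any real cohort.

Default volume size is 64×64×24; the acceptance tests run the same
statistical structure at 32×32×12 to fit a single-CPU test budget.

# Design choices that were genuinely open

* **Standardization order.** The leakage-safe default fits means/SDs on
  each training fold. Pipelines that standardize the whole table before
  splitting are common; that mode (`standardize_mode = "upfront"`) is
  provided for comparability and is mildly optimistic.
* **Honest vs reported tuning.** `evaluate()` reports, per
  hyperparameter, the same CV estimates used to select the best one —
  the conventional, slightly optimistic practice. `evaluate_nested()`
  provides the nested-CV alternative (inner-CV hyperparameter choice per
  outer fold) for when an unbiased single number is needed; it is off the
  default path because the per-hyperparameter table is itself a reported
  artifact.
* **Feature selection column order.** Selected top-k features are applied
  in original table order, not ranking order, so the k = m point of a
  selection sweep reproduces the no-selection evaluation bit for bit
  (column order perturbs both the SVM floating-point accumulation and the
  forest's feature-sampling RNG stream).
* **Configuration format.** The run configuration round-trips through
  JSON (`jsonlite`), with unknown keys rejected at any level. JSON was
  chosen over YAML because lossless round-tripping is the actual
  requirement and a maintained parser ships with every scientific R
  installation.
* **NIfTI support** is a minimal NIfTI-1 reader/writer (datatypes uint8,
  int16, int32, float32, float64; scaling slope/intercept honoured; both
  endiannesses; gzip by extension). It is deliberately not a general
  neuroimaging I/O layer: no qform rotation decoding, no resampling, no
  NIfTI-2.

# Known limitations

* Exact numeric parity with other radiomics toolboxes is not claimable:
  quantization ranges, entropy bases and subband discretisation vary
  across implementations, and most are unstated in publications. The
  conventions above are fixed and tested instead.
* The Mann-Whitney exact path is only used for very small samples; at
  typical cohort sizes the tie-corrected normal approximation is in
  effect (its type-I calibration is covered by the acceptance suite).
* MIC uses the equipartition-plus-DP approximation, not an exhaustive
  grid search; scores can sit marginally below the exhaustive optimum.
* The CLI chains stages through files in one output directory; it is a
  reproducibility tool, not a workflow engine — no parallelism, no
  partial-stage caching beyond the stage outputs themselves.
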