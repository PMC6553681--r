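# Synthetic two-class phantom cohorts: 3D volumes whose masked regions
# differ in spatial texture (correlation length and local contrast), not in
# mean intensity, at a controllable effect size.

# evaluate expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# separable Gaussian smoothing of a 3D array (boundary-renormalized kernel)
smooth_field <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  rad <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-rad):rad)^2 / (2 * sigma^2))
  smooth_axis <- function(a, ax) {
    n <- dim(a)[ax]
    K <- matrix(0, n, n)
    for (o in (-rad):rad) {
      idx <- seq_len(n)
      j <- idx + o
      ok <- j >= 1L & j <= n
      K[cbind(idx[ok], j[ok])] <- K[cbind(idx[ok], j[ok])] + k[o + rad + 1L]
    }
    K <- K / rowSums(K)
    per <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, per), dim(a)[ax])
    out <- array(K %*% m, dim(a)[per])
    aperm(out, order(per))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Specification of a synthetic phantom cohort
#'
#' Class differences are induced by the smoothing scale (spatial correlation
#' length) and local-contrast multiplier of a seeded Gaussian random field;
#' the base intensity is shared so first-order mean carries no signal. With
#' `effect_size = 0` both classes draw from one distribution. Class 1 uses
#' smoothing scale `smoothing_scale * (1 + effect_size)` and contrast
#' `contrast * (1 + 0.5 * effect_size)`.
#'
#' @param volume_shape integer vector of 3 voxel counts, each >= 8.
#' @param mask_kind "blob" (one connected irregular region), "shell"
#'   (a hollow spherical band), or "scatter" (many small clusters, emulating
#'   white-matter-hyperintensity lesion maps).
#' @param mask_fraction expected in-mask voxel fraction, in (0, 0.5].
#' @param base_intensity mean grey level inside the volume (arbitrary units).
#' @param noise_sd SD of voxel-wise white noise (arbitrary units).
#' @param smoothing_scale class-0 Gaussian smoothing scale in voxels.
#' @param contrast class-0 amplitude of the smoothed texture component.
#' @param effect_size scalar >= 0 separating the two classes.
#' @param subject_jitter_sd SD of the per-subject log-scale jitter applied to
#'   the smoothing scale (within-class heterogeneity).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64L, 64L, 24L),
                         mask_kind = c("blob", "shell", "scatter"),
                         mask_fraction = 0.1,
                         base_intensity = 100,
                         noise_sd = 2,
                         smoothing_scale = 0.8,
                         contrast = 10,
                         effect_size = 0,
                         subject_jitter_sd = 0.05) {
  mask_kind <- match.arg(mask_kind)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 8L))
    rt_error("volume_shape must be 3 components, each >= 8", "radtex_invalid_spec")
  if (!(mask_fraction > 0 && mask_fraction <= 0.5))
    rt_error("mask_fraction must be in (0, 0.5]", "radtex_invalid_spec")
  if (effect_size < 0)
    rt_error("effect_size must be >= 0", "radtex_invalid_spec")
  structure(list(volume_shape = volume_shape, mask_kind = mask_kind,
                 mask_fraction = mask_fraction,
                 base_intensity = base_intensity, noise_sd = noise_sd,
                 smoothing_scale = smoothing_scale, contrast = contrast,
                 effect_size = effect_size,
                 subject_jitter_sd = subject_jitter_sd),
            class = "phantom_spec")
}

# per-class generative parameters
class_params <- function(spec, class_label) {
  stopifnot(class_label %in% c(0L, 1L))
  if (class_label == 0L)
    list(scale = spec$smoothing_scale, contrast = spec$contrast)
  else
    list(scale = spec$smoothing_scale * (1 + spec$effect_size),
         contrast = spec$contrast * (1 + 0.5 * spec$effect_size))
}

#' A 3D grey-level volume with a co-registered binary ROI mask
#'
#' @param intensities 3D non-negative finite numeric array.
#' @param mask 3D binary (0/1 or logical) array of identical shape with at
#'   least one nonzero voxel.
#' @param subject_id,sequence_tag,tissue_tag metadata strings.
#' @return object of class `volume_with_mask`.
#' @export
volume_with_mask <- function(intensities, mask, subject_id = "S000",
                             sequence_tag = "FLAIR", tissue_tag = "NAWM") {
  if (!identical(dim(intensities), dim(mask)))
    rt_error("intensities and mask shapes differ", "radtex_shape_mismatch")
  if (!any(mask > 0))
    rt_error(paste0("mask of subject ", subject_id, " has no voxel"),
             "radtex_empty_region")
  if (any(!is.finite(intensities)))
    rt_error("intensities must be finite", "radtex_invalid_input")
  structure(list(intensities = intensities,
                 mask = array(as.integer(mask > 0), dim(mask)),
                 subject_id = subject_id, sequence_tag = sequence_tag,
                 tissue_tag = tissue_tag),
            class = "volume_with_mask")
}

#' @export
print.volume_with_mask <- function(x, ...) {
  cat("volume_with_mask", x$subject_id, x$sequence_tag, x$tissue_tag, ":",
      paste(dim(x$intensities), collapse = "x"), "voxels,",
      sum(x$mask), "in mask\n")
  invisible(x)
}

# build a mask of the requested kind and expected voxel fraction
make_mask <- function(spec, seed) {
  d <- spec$volume_shape
  with_seed(seed, {
    ax <- lapply(d, function(n) (seq_len(n) - (n + 1) / 2) / (n / 2))
    dist <- sqrt(outer(outer(ax[[1]]^2, ax[[2]]^2, "+"), ax[[3]]^2, "+"))
    f <- switch(spec$mask_kind,
      blob = smooth_field(array(rnorm(prod(d)), d), 3) * 1.2 + (1 - dist),
      scatter = smooth_field(array(rnorm(prod(d)), d), 0.8),
      shell = -abs(dist - 0.55) +
        0.15 * smooth_field(array(rnorm(prod(d)), d), 2))
    thr <- stats::quantile(f, 1 - spec$mask_fraction, names = FALSE)
    m <- f >= thr
    if (!any(m)) m[which.max(f)] <- TRUE
    array(as.integer(m), d)
  })
}

#' Generate one phantom volume with mask
#'
#' Deterministic given `(spec, class_label, seed)`. The masked texture is a
#' smoothed Gaussian random field with class-dependent correlation length and
#' amplitude plus white noise, offset to a shared non-negative base level.
#'
#' @param spec a [phantom_spec()].
#' @param class_label 0 or 1.
#' @param seed integer seed.
#' @param subject_id,sequence_tag,tissue_tag metadata for the result.
#' @param param_jitter per-subject multiplicative log-jitter on the smoothing
#'   scale (0 = exact class parameters).
#' @return a [volume_with_mask()].
#' @export
generate_phantom <- function(spec, class_label, seed,
                             subject_id = "S000", sequence_tag = "FLAIR",
                             tissue_tag = "NAWM", param_jitter = 0) {
  if (!inherits(spec, "phantom_spec"))
    rt_error("spec must be a phantom_spec", "radtex_invalid_spec")
  p <- class_params(spec, as.integer(class_label))
  scale <- p$scale * exp(param_jitter)
  d <- spec$volume_shape
  vox <- with_seed(spawn_seed(seed, 2L), {
    tex <- smooth_field(array(rnorm(prod(d)), d), scale)
    tex <- tex / max(stats::sd(tex), 1e-12)
    spec$base_intensity + p$contrast * tex +
      spec$noise_sd * array(rnorm(prod(d)), d)
  })
  vox[vox < 0] <- 0
  m <- make_mask(spec, spawn_seed(seed, 1L))
  volume_with_mask(vox, m, subject_id, sequence_tag, tissue_tag)
}

#' Generate a balanced two-class phantom cohort with covariates
#'
#' Produces `2 * n_per_class` subjects with balanced labels. The first
#' covariate (`cov_texture`) has a configurable true correlation
#' `covariate_rho` with the class-separating texture parameter (the subject's
#' log smoothing scale); the remaining covariates are independent noise.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_class subjects per class (>= 1).
#' @param base_seed integer seed; all per-subject seeds derive from it via
#'   [spawn_seed()].
#' @param covariate_rho true correlation of `cov_texture` with the subject
#'   texture parameter (default 0.5).
#' @param n_noise_covariates number of additional independent covariates.
#' @param sequence_tag,tissue_tag metadata applied to every volume.
#' @return list with `volumes` (list of [volume_with_mask()]), `labels`
#'   (integer 0/1), and `covariates` (data.frame with `subject_id`, `label`,
#'   `cov_texture`, `cov_noise*`).
#' @export
generate_cohort <- function(spec, n_per_class, base_seed,
                            covariate_rho = 0.5, n_noise_covariates = 2L,
                            sequence_tag = "FLAIR", tissue_tag = "NAWM") {
  if (n_per_class < 1L) rt_error("n_per_class must be >= 1", "radtex_invalid_spec")
  n <- 2L * as.integer(n_per_class)
  labels <- rep(c(0L, 1L), each = n_per_class)
  ids <- sprintf("S%03d", seq_len(n))
  jit <- with_seed(spawn_seed(base_seed, 9001L),
                   rnorm(n, 0, spec$subject_jitter_sd))
  vols <- vector("list", n)
  true_param <- numeric(n)
  for (i in seq_len(n)) {
    vols[[i]] <- generate_phantom(spec, labels[i], spawn_seed(base_seed, i),
                                  subject_id = ids[i],
                                  sequence_tag = sequence_tag,
                                  tissue_tag = tissue_tag,
                                  param_jitter = jit[i])
    true_param[i] <- log(class_params(spec, labels[i])$scale) + jit[i]
  }
  covs <- with_seed(spawn_seed(base_seed, 9002L), {
    z <- as.numeric(scale(true_param))
    if (!all(is.finite(z))) z <- rep(0, n)   # zero-variance parameter
    ct <- covariate_rho * z + sqrt(1 - covariate_rho^2) * rnorm(n)
    cn <- matrix(rnorm(n * n_noise_covariates), n)
    df <- data.frame(subject_id = ids, label = labels, cov_texture = ct)
    if (n_noise_covariates > 0) {
      colnames(cn) <- paste0("cov_noise", seq_len(n_noise_covariates))
      df <- cbind(df, cn)
    }
    df
  })
  list(volumes = vols, labels = labels, covariates = covs)
}
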