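# The 114-descriptor set: 13 GLCM + 11 GLRLM + 40 LBP + 26 WSF + 24 WCF.

#' Names of the 114 texture features, in canonical order
#'
#' @param family optional subset: one of "GLCM", "GLRLM", "LBP", "WSF", "WCF".
#' @return character vector of feature names (length 114, or the family size
#'   13/11/40/26/24).
#' @export
feature_names <- function(family = NULL) {
  nm <- list(
    GLCM  = paste0("GLCM_", glcm_feature_names),
    GLRLM = paste0("GLRLM_", glrlm_feature_names),
    LBP   = lbp_feature_names,
    WSF   = paste0("WSF_", wsf_feature_names),
    WCF   = paste0("WCF_", wcf_feature_names))
  if (is.null(family)) return(unlist(nm, use.names = FALSE))
  if (!family %in% names(nm))
    rt_error("unknown feature family", "radtex_invalid_config")
  nm[[family]]
}

#' Texture family of each feature name
#' @param names character vector of feature names.
#' @return factor with levels GLCM, GLRLM, LBP, WSF, WCF.
#' @export
feature_family <- function(names) {
  fam <- sub("_.*$", "", names)
  factor(fam, levels = c("GLCM", "GLRLM", "LBP", "WSF", "WCF"))
}

#' All 114 texture features of one masked 2D slice
#'
#' GLCM and GLRLM are computed on the slice quantized to `cfg$Ng` levels
#' (against `range` when the volume-range policy is in force), LBP on raw
#' intensities, and the wavelet families on the masked bounding-box crop.
#'
#' @param slice 2D numeric matrix.
#' @param mask 2D logical matrix, same shape, at least one `TRUE` pixel.
#' @param cfg a [texture_config()].
#' @param range optional reference intensity range for quantization.
#' @return named numeric vector of length 114 (`NA` where undefined).
#' @export
extract_slice_features <- function(slice, mask, cfg = texture_config(),
                                   range = NULL) {
  q <- quantize(slice, mask, Ng = cfg$Ng, range = range)
  g <- glcm_features(q, cfg)
  r <- glrlm_features(q, cfg)
  l <- lbp_features(slice, mask, cfg)
  ws <- wsf_features(slice, mask, cfg)
  wc <- wcf_features(slice, mask, cfg)
  out <- c(g, r, l, ws, wc)
  names(out) <- feature_names()
  out
}

#' 3D texture features of a masked volume
#'
#' Extracts the 114 2D features from every slice (third array axis by
#' default) with at least `cfg$min_mask_pixels` in-mask pixels, then
#' aggregates each feature as the median over the slices where it is finite.
#' A feature finite in no slice is `NA` with `validity = FALSE`; a volume
#' with no contributing slice returns an all-invalid vector (not an error).
#'
#' @param vol a [volume_with_mask()] (or a list with `intensities` and
#'   `mask` 3D arrays).
#' @param cfg a [texture_config()].
#' @param slice_axis array axis to slice along (default 3).
#' @return object of class `feature_vector`: list with `values` (named
#'   numeric, length 114), `validity` (named logical), and `n_slices_used`.
#' @export
extract_volume_features <- function(vol, cfg = texture_config(),
                                    slice_axis = 3L) {
  x <- vol$intensities
  m <- vol$mask
  if (!identical(dim(x), dim(m)))
    rt_error("intensity and mask shapes differ", "radtex_shape_mismatch")
  nd <- length(dim(x))
  if (nd != 3L) rt_error("expected a 3D volume", "radtex_invalid_input")
  slice_axis <- as.integer(slice_axis)
  rng <- if (cfg$range_policy == "volume" && any(m > 0)) {
    v <- x[m > 0]
    c(min(v), max(v))
  } else NULL
  ns <- dim(x)[slice_axis]
  take <- function(a, k) {
    switch(slice_axis, a[k, , ], a[, k, ], a[, , k])
  }
  per_slice <- matrix(NA_real_, 114L, 0L)
  for (k in seq_len(ns)) {
    mk <- take(m, k) > 0
    if (sum(mk) < cfg$min_mask_pixels) next
    sl <- take(x, k)
    f <- extract_slice_features(sl, mk, cfg, range = rng)
    per_slice <- cbind(per_slice, f)
  }
  vals <- apply(per_slice, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) stats::median(v) else NA_real_
  })
  if (ncol(per_slice) == 0L) vals <- rep(NA_real_, 114L)
  names(vals) <- feature_names()
  structure(list(values = vals,
                 validity = stats::setNames(is.finite(vals), feature_names()),
                 n_slices_used = ncol(per_slice)),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("feature_vector: 114 features,", sum(x$validity), "finite,",
      x$n_slices_used, "slices aggregated\n")
  invisible(x)
}
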