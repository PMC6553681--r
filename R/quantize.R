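#' Uniform grey-level quantization of a masked slice
#'
#' Maps in-mask intensities to integer levels `1..Ng` over uniform bins of a
#' reference range. The reference range defaults to the in-mask min-max of
#' the slice itself; pass `range` to share one grey scale across slices of a
#' volume (the volume-range policy). The maximum of the range maps to level
#' `Ng`; a constant region maps wholly to level 1. Pixels outside the mask
#' are `NA`.
#'
#' @param slice 2D numeric matrix of intensities (finite inside the mask).
#' @param mask 2D logical matrix, same shape, at least one `TRUE`.
#' @param Ng integer number of grey levels.
#' @param range optional length-2 numeric reference range `c(lo, hi)`.
#' @return an object of class `quantized_slice`: list with integer matrix
#'   `levels` (`NA` outside mask), logical `mask`, and `Ng`.
#' @export
quantize <- function(slice, mask, Ng = 32L, range = NULL) {
  slice <- as.matrix(slice)
  mask <- matrix(as.logical(mask), nrow(slice), ncol(slice))
  if (!identical(dim(slice), dim(mask)))
    rt_error("slice and mask shapes differ", "radtex_shape_mismatch")
  if (!any(mask)) rt_error("mask has no TRUE pixel", "radtex_empty_region")
  v <- slice[mask]
  if (any(!is.finite(v)))
    rt_error("non-finite intensities inside mask", "radtex_invalid_input")
  if (is.null(range)) range <- c(min(v), max(v))
  lo <- range[1]; hi <- range[2]
  Ng <- as.integer(Ng)
  lev <- matrix(NA_integer_, nrow(slice), ncol(slice))
  if (hi <= lo) {
    lev[mask] <- 1L
  } else {
    k <- floor((slice[mask] - lo) / (hi - lo) * Ng) + 1
    lev[mask] <- as.integer(pmin(pmax(k, 1), Ng))
  }
  structure(list(levels = lev, mask = mask, Ng = Ng), class = "quantized_slice")
}
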