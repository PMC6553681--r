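#' Texture extraction configuration
#'
#' Bundles every tunable of the per-slice texture extractors. Defaults follow
#' the conventions of 2D radiomics on thick-slice structural MRI: 32 grey
#' levels, co-occurrence distance 1 pixel averaged over the four 2D
#' directions, the original 8-neighbour local binary pattern operator, and a
#' 3-level Haar wavelet decomposition.
#'
#' @param Ng integer, number of grey levels for uniform quantization (>= 2).
#' @param d integer, co-occurrence pixel distance (>= 1).
#' @param directions numeric vector of angles in degrees; each of the four
#'   canonical directions 0, 45, 90, 135 denotes an (offset) pixel pair axis.
#' @param lbp_P integer, local binary pattern neighbour count; must be 8 (the
#'   36-bin rotation-invariant histogram is specific to 8 bits).
#' @param lbp_R numeric, local binary pattern neighbour radius; must be 1.
#' @param dwt_levels integer, wavelet decomposition depth (>= 1).
#' @param wavelet_family character; only "haar" is supported.
#' @param min_mask_pixels integer, minimum in-mask pixels for a slice to
#'   contribute to the volume aggregate. 16 guarantees a nondegenerate 3x3
#'   neighbourhood and at least one co-occurring pair.
#' @param range_policy "volume" (default) quantizes every slice against the
#'   in-mask min-max of the whole volume so slices share one grey scale;
#'   "slice" uses each slice's own range.
#' @return an object of class `texture_config`.
#' @export
texture_config <- function(Ng = 32L, d = 1L,
                           directions = c(0, 45, 90, 135),
                           lbp_P = 8L, lbp_R = 1,
                           dwt_levels = 3L, wavelet_family = "haar",
                           min_mask_pixels = 16L,
                           range_policy = c("volume", "slice")) {
  range_policy <- match.arg(range_policy)
  Ng <- as.integer(Ng); d <- as.integer(d); dwt_levels <- as.integer(dwt_levels)
  if (Ng < 2L) rt_error("Ng must be >= 2", "radtex_invalid_config")
  if (d < 1L) rt_error("d must be >= 1", "radtex_invalid_config")
  if (!all(directions %in% c(0, 45, 90, 135)))
    rt_error("directions must be a subset of {0, 45, 90, 135}", "radtex_invalid_config")
  if (as.integer(lbp_P) != 8L || lbp_R != 1)
    rt_error("only lbp_P = 8, lbp_R = 1 is supported", "radtex_invalid_config")
  if (dwt_levels < 1L) rt_error("dwt_levels must be >= 1", "radtex_invalid_config")
  if (!identical(tolower(wavelet_family), "haar"))
    rt_error("only the Haar wavelet family is supported", "radtex_invalid_config")
  structure(list(Ng = Ng, d = d, directions = directions,
                 lbp_P = 8L, lbp_R = 1, dwt_levels = dwt_levels,
                 wavelet_family = "haar",
                 min_mask_pixels = as.integer(min_mask_pixels),
                 range_policy = range_policy),
            class = "texture_config")
}

#' @export
print.texture_config <- function(x, ...) {
  cat("texture_config: Ng=", x$Ng, " d=", x$d,
      " directions={", paste(x$directions, collapse = ","), "}",
      " LBP(P=8,R=1) dwt_levels=", x$dwt_levels,
      " min_mask_pixels=", x$min_mask_pixels,
      " range_policy=", x$range_policy, "\n", sep = "")
  invisible(x)
}
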