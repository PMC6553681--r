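# Rotation-invariant local binary patterns (P = 8, R = 1).
#
# Each valid pixel (itself and its full 3x3 neighbourhood in-mask) gets the
# 8-bit code sum_p s(g_p - g_c) 2^p with s(x) = 1 iff x >= 0, computed on RAW
# intensities (no quantization; the operator only compares, so it is
# invariant under strictly increasing intensity transforms). Rotation
# invariance maps each code to the minimum over its 8 circular rotations;
# exactly 36 canonical codes exist for 8 bits.

# circular rotations of an 8-bit code
rot8 <- function(code) {
  vapply(0:7, function(k) {
    bitwAnd(bitwOr(bitwShiftL(code, k), bitwShiftR(code, 8L - k)), 255L)
  }, integer(1))
}

#' Canonical rotation-invariant codes for all 256 raw 8-bit patterns
#'
#' @return integer vector of length 256; entry `k + 1` is the minimum over
#'   the circular rotations of raw code `k`.
#' @export
lbp_canonical_table <- function() {
  vapply(0:255, function(code) min(rot8(code)), integer(1))
}

#' The 36 canonical 8-bit rotation-invariant pattern codes, ascending
#' @return sorted integer vector of length 36.
#' @export
lbp_canonical_codes <- function() sort(unique(lbp_canonical_table()))

# neighbour offsets p = 0..7, counter-clockwise from East; (row, col)
lbp_offsets <- rbind(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
                     c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))

#' Canonical LBP code map of a masked slice
#'
#' @param slice 2D numeric matrix of raw intensities.
#' @param mask 2D logical matrix, same shape.
#' @return integer matrix of canonical codes; `NA` where the pixel or any of
#'   its 8 neighbours is outside the mask (or the image).
#' @export
lbp_code_map <- function(slice, mask) {
  slice <- as.matrix(slice)
  mask <- matrix(as.logical(mask), nrow(slice), ncol(slice))
  nr <- nrow(slice); nc <- ncol(slice)
  code <- matrix(0L, nr, nc)
  valid <- mask
  if (nr < 3L || nc < 3L) {
    valid[] <- FALSE
  } else {
    inner <- 2:(nr - 1)
    innc <- 2:(nc - 1)
    v <- matrix(FALSE, nr, nc)
    v[inner, innc] <- mask[inner, innc]
    ctr <- slice[inner, innc, drop = FALSE]
    for (p in seq_len(8L)) {
      o <- lbp_offsets[p, ]
      nb <- slice[inner + o[1], innc + o[2], drop = FALSE]
      nbm <- mask[inner + o[1], innc + o[2], drop = FALSE]
      v[inner, innc] <- v[inner, innc] & nbm
      bit <- (nb - ctr >= 0) * 2^(p - 1L)
      code[inner, innc] <- code[inner, innc] + as.integer(bit)
    }
    valid <- v
  }
  canon <- lbp_canonical_table()
  out <- matrix(NA_integer_, nr, nc)
  out[valid] <- canon[code[valid] + 1L]
  out
}

lbp_feature_names <- c(paste0("LBP_", 1:36),
                       "LBP_Median", "LBP_Variance", "LBP_Skewness", "LBP_Kurtosis")

#' LBP texture features of a masked slice
#'
#' 36 normalized canonical-pattern histogram frequencies (bins are the 36
#' canonical codes sorted ascending, mapped to `LBP_1..LBP_36`) plus the
#' median, variance, skewness and kurtosis of the canonical-code map over
#' valid pixels. Variance is the sample variance; skewness and kurtosis are
#' moment-based with non-excess kurtosis. Zero valid pixels gives 40 `NA`s.
#'
#' @param slice 2D numeric matrix of raw intensities.
#' @param mask 2D logical matrix, same shape.
#' @param cfg a [texture_config()] (only the P = 8, R = 1 operator is used).
#' @return named numeric vector of 40 features.
#' @export
lbp_features <- function(slice, mask, cfg = texture_config()) {
  out <- rep(NA_real_, 40)
  names(out) <- lbp_feature_names
  cm <- lbp_code_map(slice, mask)
  codes <- cm[!is.na(cm)]
  n <- length(codes)
  if (n == 0L) return(out)
  bins <- lbp_canonical_codes()
  h <- tabulate(match(codes, bins), nbins = 36L) / n
  out[1:36] <- h
  out["LBP_Median"] <- stats::median(codes)
  out["LBP_Variance"] <- if (n > 1L) stats::var(codes) else 0
  m <- mean(codes)
  m2 <- mean((codes - m)^2)
  if (m2 > 0) {
    out["LBP_Skewness"] <- mean((codes - m)^3) / m2^1.5
    out["LBP_Kurtosis"] <- mean((codes - m)^4) / m2^2
  }
  out
}
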