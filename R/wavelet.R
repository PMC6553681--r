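# Orthonormal 2D Haar decomposition and the two wavelet feature families.
#
# Wavelet input: the mask bounding-box crop with out-of-mask pixels replaced
# by the in-mask mean (zero-fill would inject a spurious edge). Odd
# dimensions are edge-replicated to even at each level. Level i+1 decomposes
# the approximation LL_i.

pad_even <- function(x) {
  if (nrow(x) %% 2L == 1L) x <- rbind(x, x[nrow(x), , drop = FALSE])
  if (ncol(x) %% 2L == 1L) x <- cbind(x, x[, ncol(x), drop = FALSE])
  x
}

haar_step <- function(x) {
  x <- pad_even(x)
  oc <- seq(1L, ncol(x), by = 2L)
  Lc <- (x[, oc, drop = FALSE] + x[, oc + 1L, drop = FALSE]) / sqrt(2)
  Hc <- (x[, oc, drop = FALSE] - x[, oc + 1L, drop = FALSE]) / sqrt(2)
  or <- seq(1L, nrow(x), by = 2L)
  lo <- function(m) (m[or, , drop = FALSE] + m[or + 1L, , drop = FALSE]) / sqrt(2)
  hi <- function(m) (m[or, , drop = FALSE] - m[or + 1L, , drop = FALSE]) / sqrt(2)
  list(LL = lo(Lc), LH = hi(Lc), HL = lo(Hc), HH = hi(Hc), padded = x)
}

haar_unstep <- function(s) {
  r2 <- 2L * nrow(s$LL); c2 <- 2L * ncol(s$LL)
  Lc <- matrix(0, r2, ncol(s$LL)); Hc <- matrix(0, r2, ncol(s$LL))
  or <- seq(1L, r2, by = 2L)
  Lc[or, ] <- (s$LL + s$LH) / sqrt(2); Lc[or + 1L, ] <- (s$LL - s$LH) / sqrt(2)
  Hc[or, ] <- (s$HL + s$HH) / sqrt(2); Hc[or + 1L, ] <- (s$HL - s$HH) / sqrt(2)
  x <- matrix(0, r2, c2)
  oc <- seq(1L, c2, by = 2L)
  x[, oc] <- (Lc + Hc) / sqrt(2); x[, oc + 1L] <- (Lc - Hc) / sqrt(2)
  x
}

#' Multi-level orthonormal 2D Haar decomposition
#'
#' @param image 2D numeric matrix, all finite.
#' @param levels requested decomposition depth (>= 1).
#' @return object of class `haar_decomposition`: list with `subbands` (a
#'   named list `LL1, LH1, HL1, HH1, LL2, ...`), `levels_done`, and
#'   `early_stop` (`TRUE` when the image fell below 2x2 before reaching the
#'   requested depth).
#' @export
haar_decompose <- function(image, levels = 3L) {
  image <- as.matrix(image)
  if (any(!is.finite(image)))
    rt_error("image must be finite", "radtex_invalid_input")
  levels <- as.integer(levels)
  if (levels < 1L) rt_error("levels must be >= 1", "radtex_invalid_config")
  sub <- list()
  cur <- image
  done <- 0L
  for (i in seq_len(levels)) {
    if (nrow(cur) < 2L || ncol(cur) < 2L) break
    s <- haar_step(cur)
    sub[[paste0("LL", i)]] <- s$LL
    sub[[paste0("LH", i)]] <- s$LH
    sub[[paste0("HL", i)]] <- s$HL
    sub[[paste0("HH", i)]] <- s$HH
    cur <- s$LL
    done <- i
  }
  structure(list(subbands = sub, levels_done = done,
                 early_stop = done < levels),
            class = "haar_decomposition")
}

#' Inverse of a single-level slice of a Haar decomposition
#'
#' Reconstructs the (padded) input of level `level` from its four subbands.
#' @param dec a `haar_decomposition`.
#' @param level level to invert (default 1).
#' @return numeric matrix (the padded input at that level).
#' @export
haar_reconstruct <- function(dec, level = 1L) {
  nm <- paste0(c("LL", "LH", "HL", "HH"), level)
  if (!all(nm %in% names(dec$subbands)))
    rt_error("level not present in decomposition", "radtex_invalid_input")
  haar_unstep(list(LL = dec$subbands[[nm[1]]], LH = dec$subbands[[nm[2]]],
                   HL = dec$subbands[[nm[3]]], HH = dec$subbands[[nm[4]]]))
}

# mask bounding-box crop with out-of-mask pixels set to the in-mask mean
wavelet_input <- function(slice, mask) {
  rr <- range(which(rowSums(mask) > 0))
  cc <- range(which(colSums(mask) > 0))
  x <- slice[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  m <- mask[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  x[!m] <- mean(x[m])
  x
}

wsf_feature_names <- c(
  "Mean_OI", "SD_OI",
  paste0("Mean_", c(t(outer(c("LL", "LH", "HL", "HH"), 1:3, paste0)))),
  paste0("SD_",   c(t(outer(c("LL", "LH", "HL", "HH"), 1:3, paste0)))))

#' Wavelet statistical features (26 values)
#'
#' Mean and sample SD of the in-mask intensities of the original image plus
#' mean and SD of each subband after `dwt_levels` (default 3) Haar
#' decomposition levels of the masked bounding-box crop. Subbands missing
#' because the region is too small stay `NA`.
#'
#' @param slice 2D numeric matrix.
#' @param mask 2D logical matrix, same shape, at least one `TRUE`.
#' @param cfg a [texture_config()].
#' @return named numeric vector of 26 features.
#' @export
wsf_features <- function(slice, mask, cfg = texture_config()) {
  out <- rep(NA_real_, 26)
  names(out) <- wsf_feature_names
  v <- slice[mask]
  out["Mean_OI"] <- mean(v)
  out["SD_OI"] <- if (length(v) > 1L) stats::sd(v) else NA_real_
  x <- wavelet_input(slice, mask)
  dec <- haar_decompose_safe(x, cfg$dwt_levels)
  for (i in seq_len(cfg$dwt_levels)) {
    for (b in c("LL", "LH", "HL", "HH")) {
      sb <- dec$subbands[[paste0(b, i)]]
      if (!is.null(sb)) {
        out[paste0("Mean_", b, i)] <- mean(sb)
        out[paste0("SD_", b, i)] <- if (length(sb) > 1L) stats::sd(c(sb)) else NA_real_
      }
    }
  }
  out
}

# decomposition that degrades to "no subbands" instead of erroring on tiny input
haar_decompose_safe <- function(x, levels) {
  if (nrow(x) < 2L || ncol(x) < 2L)
    return(list(subbands = list(), levels_done = 0L, early_stop = TRUE))
  haar_decompose(x, levels)
}

wcf_subbands <- c("LL1", "LH1", "HL1", "HH1")
wcf_stats <- c("Energy", "Contrast", "Correlation", "Homogeneity",
               "Entropy", "Variance")
wcf_feature_names <- c(outer(wcf_stats, wcf_subbands, paste, sep = "_"))

#' Wavelet co-occurrence features (24 values)
#'
#' Six GLCM statistics (energy, contrast, correlation, homogeneity, entropy,
#' variance) of each level-1 Haar subband of the masked bounding-box crop.
#' Each subband is uniformly quantized to `Ng` levels over its own min-max
#' (signed coefficients have no common reference range) and its GLCM computed
#' and direction-averaged exactly as for the original image.
#'
#' @param slice 2D numeric matrix.
#' @param mask 2D logical matrix, same shape, at least one `TRUE`.
#' @param cfg a [texture_config()].
#' @return named numeric vector of 24 features.
#' @export
wcf_features <- function(slice, mask, cfg = texture_config()) {
  out <- rep(NA_real_, 24)
  names(out) <- wcf_feature_names
  x <- wavelet_input(slice, mask)
  dec <- haar_decompose_safe(x, 1L)
  for (b in wcf_subbands) {
    sb <- dec$subbands[[b]]
    if (is.null(sb)) next
    q <- quantize(sb, matrix(TRUE, nrow(sb), ncol(sb)), Ng = cfg$Ng)
    f <- glcm_features(q, cfg)
    out[paste0(wcf_stats, "_", b)] <- f[wcf_stats]
  }
  out
}
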