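# Grey-level run-length matrices and their 11 statistics.
#
# A run is a maximal sequence of equal-level in-mask pixels along a direction;
# mask boundaries break runs. The run-percentage denominator is the in-mask
# pixel count. Per-direction statistics are averaged over the four directions.

# extract the direction's scan lines as a list of level vectors (NA = gap)
glrlm_lines <- function(L, theta) {
  nr <- nrow(L); nc <- ncol(L)
  switch(as.character(theta),
         "0"   = lapply(seq_len(nr), function(r) L[r, ]),
         "90"  = lapply(seq_len(nc), function(c) L[, c]),
         # split() keeps linear-index order inside each group, which walks a
         # diagonal line monotonically -- good enough for run extraction
         "45"  = lapply(split(seq_along(L), c(row(L) + col(L))),
                        function(ii) L[ii]),
         "135" = lapply(split(seq_along(L), c(row(L) - col(L))),
                        function(ii) L[ii]),
         rt_error("unsupported direction", "radtex_invalid_config"))
}

#' Run-length matrix of a quantized slice for one direction
#'
#' @param q a `quantized_slice`.
#' @param theta direction in degrees (0, 45, 90 or 135).
#' @return list with `counts` (Ng x Lmax run counts; Lmax = longest possible
#'   run) and `n_pixels` (in-mask pixel count).
#' @export
glrlm_matrix <- function(q, theta) {
  L <- q$levels
  lines <- glrlm_lines(L, theta)
  lmax <- max(lengths(lines), 1L)
  # concatenate lines with NA separators, one rle pass
  flat <- unlist(lapply(lines, function(v) c(v, NA_integer_)), use.names = FALSE)
  r <- rle(ifelse(is.na(flat), -1L, flat))
  keep <- r$values != -1L
  lev <- r$values[keep]; len <- r$lengths[keep]
  counts <- matrix(0, q$Ng, lmax)
  if (length(lev)) {
    tab <- tabulate((lev - 1L) * lmax + len, nbins = q$Ng * lmax)
    counts <- matrix(tab, q$Ng, lmax, byrow = TRUE)
  }
  list(counts = counts, n_pixels = sum(!is.na(L)))
}

glrlm_feature_names <- c("SRE", "LRE", "GLN", "RLN", "RP",
                         "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

# 11 statistics from one run-length matrix
glrlm_stats <- function(counts, n_pixels) {
  out <- rep(NA_real_, 11)
  names(out) <- glrlm_feature_names
  nr <- sum(counts)
  if (nr <= 0 || n_pixels <= 0) return(out)
  gl <- seq_len(nrow(counts))          # grey level i
  rl <- seq_len(ncol(counts))          # run length l
  gi2 <- matrix(gl^2, nrow(counts), ncol(counts))
  rl2 <- matrix(rl^2, nrow(counts), ncol(counts), byrow = TRUE)
  out["SRE"]   <- sum(counts / rl2) / nr
  out["LRE"]   <- sum(counts * rl2) / nr
  out["GLN"]   <- sum(rowSums(counts)^2) / nr
  out["RLN"]   <- sum(colSums(counts)^2) / nr
  out["RP"]    <- nr / n_pixels
  out["LGRE"]  <- sum(counts / gi2) / nr
  out["HGRE"]  <- sum(counts * gi2) / nr
  out["SRLGE"] <- sum(counts / (gi2 * rl2)) / nr
  out["SRHGE"] <- sum(counts * gi2 / rl2) / nr
  out["LRLGE"] <- sum(counts * rl2 / gi2) / nr
  out["LRHGE"] <- sum(counts * gi2 * rl2) / nr
  out
}

#' GLRLM texture features of a quantized slice
#'
#' The 11 run-length statistics per direction, each averaged over the finite
#' directions. No run in any direction yields an all-`NA` vector.
#'
#' @param q a `quantized_slice`.
#' @param cfg a [texture_config()].
#' @return named numeric vector of 11 features.
#' @export
glrlm_features <- function(q, cfg = texture_config()) {
  per_dir <- vapply(cfg$directions, function(th) {
    m <- glrlm_matrix(q, th)
    glrlm_stats(m$counts, m$n_pixels)
  }, numeric(11))
  apply(per_dir, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
}
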