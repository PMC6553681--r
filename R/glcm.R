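# Grey-level co-occurrence matrices and the 13 Haralick statistics.
#
# Conventions: only ordered pixel pairs with BOTH members in-mask contribute;
# each directional count matrix is symmetrised by adding its transpose before
# normalization (so 0 and 180 degrees coincide); entropies use log base 2;
# the 13 per-direction statistics are averaged over the four directions
# (features averaged, not matrices), skipping non-finite directions.

# direction angle (degrees) -> (row, col) offset at distance d
dir_offset <- function(theta, d) {
  switch(as.character(theta),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         rt_error("unsupported direction", "radtex_invalid_config"))
}

#' Co-occurrence matrix of a quantized slice for one direction
#'
#' @param q a `quantized_slice`.
#' @param theta direction in degrees (0, 45, 90 or 135).
#' @param d pixel distance.
#' @return list with `counts` (Ng x Ng symmetrised pair counts) and
#'   `p` (normalized probabilities; all-`NA` if no pair exists).
#' @export
glcm_matrix <- function(q, theta, d = 1L) {
  Ng <- q$Ng
  L <- q$levels
  off <- dir_offset(theta, as.integer(d))
  nr <- nrow(L); nc <- ncol(L)
  r1 <- max(1L, 1L - off[1]); r2 <- min(nr, nr - off[1])
  c1 <- max(1L, 1L - off[2]); c2 <- min(nc, nc - off[2])
  counts <- matrix(0, Ng, Ng)
  if (r1 <= r2 && c1 <= c2) {
    a <- L[r1:r2, c1:c2, drop = FALSE]
    b <- L[(r1 + off[1]):(r2 + off[1]), (c1 + off[2]):(c2 + off[2]), drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (any(ok)) {
      idx <- (a[ok] - 1L) * Ng + b[ok]
      tab <- tabulate(idx, nbins = Ng * Ng)
      counts <- matrix(tab, Ng, Ng, byrow = TRUE)
    }
  }
  counts <- counts + t(counts)          # symmetrise
  tot <- sum(counts)
  p <- if (tot > 0) counts / tot else matrix(NA_real_, Ng, Ng)
  list(counts = counts, p = p)
}

glcm_feature_names <- c("Energy", "Contrast", "Correlation", "Variance",
                        "Homogeneity", "SumAverage", "SumVariance",
                        "SumEntropy", "Entropy", "DifferenceVariance",
                        "DifferenceEntropy", "FIMC", "SIMC")

# 13 Haralick statistics from one normalized symmetric GLCM
glcm_stats <- function(p) {
  Ng <- nrow(p)
  out <- rep(NA_real_, 13)
  names(out) <- glcm_feature_names
  if (!is.finite(sum(p))) return(out)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(p)                       # == py by symmetry
  py <- colSums(p)
  mu_x <- sum(seq_len(Ng) * px); mu_y <- sum(seq_len(Ng) * py)
  sd_x <- sqrt(sum((seq_len(Ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(Ng) - mu_y)^2 * py))
  lg <- function(x) ifelse(x > 0, log2(x), 0)
  # sum and difference distributions
  ks <- 2:(2 * Ng)
  pxy_sum <- sapply(ks, function(k) sum(p[i + j == k]))
  kd <- 0:(Ng - 1)
  pxy_dif <- sapply(kd, function(k) sum(p[abs(i - j) == k]))

  out["Energy"] <- sum(p^2)
  out["Contrast"] <- sum((i - j)^2 * p)
  out["Correlation"] <- if (sd_x > 0 && sd_y > 0)
    (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y) else NA_real_
  out["Variance"] <- sum((i - mu_x)^2 * p)
  out["Homogeneity"] <- sum(p / (1 + (i - j)^2))
  sa <- sum(ks * pxy_sum)
  out["SumAverage"] <- sa
  out["SumVariance"] <- sum((ks - sa)^2 * pxy_sum)
  out["SumEntropy"] <- -sum(pxy_sum * lg(pxy_sum))
  hxy <- -sum(p * lg(p))
  out["Entropy"] <- hxy
  md <- sum(kd * pxy_dif)
  out["DifferenceVariance"] <- sum((kd - md)^2 * pxy_dif)
  out["DifferenceEntropy"] <- -sum(pxy_dif * lg(pxy_dif))
  hx <- -sum(px * lg(px)); hy <- -sum(py * lg(py))
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * lg(pxpy))
  hxy2 <- -sum(pxpy * lg(pxpy))
  out["FIMC"] <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else NA_real_
  out["SIMC"] <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  out
}

#' GLCM texture features of a quantized slice
#'
#' Computes the 13 Haralick statistics per direction and averages each
#' statistic over the finite directions; a statistic that is non-finite in
#' every direction stays `NA`. Fewer than one co-occurring pair in every
#' direction yields an all-`NA` vector (the documented invalid-feature path),
#' not an error.
#'
#' @param q a `quantized_slice`.
#' @param cfg a [texture_config()].
#' @return named numeric vector of 13 features.
#' @export
glcm_features <- function(q, cfg = texture_config()) {
  per_dir <- vapply(cfg$directions,
                    function(th) glcm_stats(glcm_matrix(q, th, cfg$d)$p),
                    numeric(13))
  apply(per_dir, 1L, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) mean(v) else NA_real_
  })
}
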