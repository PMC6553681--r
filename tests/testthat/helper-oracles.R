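# Independent brute-force oracles: scalar loops and first-principles
# formulas, deliberately sharing no code with the package implementations.

# ---- GLCM oracle: O(n^2) ordered-pair enumeration -------------------------

oracle_glcm_counts <- function(levels, d, theta) {
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  Ng <- max(levels, na.rm = TRUE)
  C <- matrix(0, Ng, Ng)
  nr <- nrow(levels); nc <- ncol(levels)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    a <- levels[r, c]; b <- levels[r2, c2]
    if (is.na(a) || is.na(b)) next
    C[a, b] <- C[a, b] + 1
    C[b, a] <- C[b, a] + 1           # symmetrise pair by pair
  }
  C
}

oracle_glcm_stats <- function(C) {
  Ng <- nrow(C)
  tot <- sum(C)
  out <- rep(NA_real_, 13)
  names(out) <- c("Energy", "Contrast", "Correlation", "Variance",
                  "Homogeneity", "SumAverage", "SumVariance", "SumEntropy",
                  "Entropy", "DifferenceVariance", "DifferenceEntropy",
                  "FIMC", "SIMC")
  if (tot == 0) return(out)
  p <- C / tot
  px <- rep(0, Ng); py <- rep(0, Ng)
  for (i in 1:Ng) for (j in 1:Ng) { px[i] <- px[i] + p[i, j]; py[j] <- py[j] + p[i, j] }
  mux <- sum((1:Ng) * px); muy <- sum((1:Ng) * py)
  sx <- sqrt(sum(((1:Ng) - mux)^2 * px)); sy <- sqrt(sum(((1:Ng) - muy)^2 * py))
  psum <- rep(0, 2 * Ng); pdif <- rep(0, Ng)
  e <- ct <- co <- va <- ho <- en <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    pij <- p[i, j]
    e <- e + pij^2
    ct <- ct + (i - j)^2 * pij
    va <- va + (i - mux)^2 * pij
    ho <- ho + pij / (1 + (i - j)^2)
    if (pij > 0) en <- en - pij * log2(pij)
    co <- co + i * j * pij
    psum[i + j] <- psum[i + j] + pij
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + pij
  }
  out["Energy"] <- e; out["Contrast"] <- ct
  out["Correlation"] <- if (sx > 0 && sy > 0) (co - mux * muy) / (sx * sy) else NA
  out["Variance"] <- va; out["Homogeneity"] <- ho; out["Entropy"] <- en
  sa <- 0; for (k in 2:(2 * Ng)) sa <- sa + k * psum[k]
  out["SumAverage"] <- sa
  sv <- 0; se <- 0
  for (k in 2:(2 * Ng)) {
    sv <- sv + (k - sa)^2 * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  }
  out["SumVariance"] <- sv; out["SumEntropy"] <- se
  md <- sum((0:(Ng - 1)) * pdif)
  dv <- 0; de <- 0
  for (k in 0:(Ng - 1)) {
    dv <- dv + (k - md)^2 * pdif[k + 1]
    if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * log2(pdif[k + 1])
  }
  out["DifferenceVariance"] <- dv; out["DifferenceEntropy"] <- de
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  out["FIMC"] <- if (max(hx, hy) > 0) (en - hxy1) / max(hx, hy) else NA
  out["SIMC"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - en))))
  out
}

oracle_glcm_features <- function(levels, d = 1, dirs = c(0, 45, 90, 135)) {
  per <- sapply(dirs, function(th)
    oracle_glcm_stats(oracle_glcm_counts(levels, d, th)))
  apply(per, 1, function(v) { v <- v[is.finite(v)]; if (length(v)) mean(v) else NA_real_ })
}

# ---- GLRLM oracle: explicit per-line run scanning -------------------------

oracle_glrlm_runs <- function(levels, theta) {
  nr <- nrow(levels); nc <- ncol(levels)
  step <- switch(as.character(theta),
                 "0" = c(0, 1), "90" = c(1, 0), "45" = c(-1, 1),
                 "135" = c(1, 1))
  starts <- list()
  for (r in 1:nr) for (c in 1:nc) {
    pr <- r - step[1]; pc <- c - step[2]
    if (pr < 1 || pr > nr || pc < 1 || pc > nc)
      starts[[length(starts) + 1]] <- c(r, c)
  }
  runs <- list()
  for (s in starts) {
    r <- s[1]; c <- s[2]
    cur <- NA; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- levels[r, c]
      if (!is.na(v) && !is.na(cur) && v == cur) len <- len + 1
      else {
        if (!is.na(cur) && len > 0) runs[[length(runs) + 1]] <- c(cur, len)
        cur <- v; len <- if (is.na(v)) 0 else 1
      }
      r <- r + step[1]; c <- c + step[2]
    }
    if (!is.na(cur) && len > 0) runs[[length(runs) + 1]] <- c(cur, len)
  }
  if (!length(runs)) return(matrix(0, max(levels, na.rm = TRUE), 1))
  runs <- do.call(rbind, runs)
  Ng <- max(levels, na.rm = TRUE)
  Lmax <- max(nr, nc)
  M <- matrix(0, Ng, Lmax)
  for (k in seq_len(nrow(runs))) M[runs[k, 1], runs[k, 2]] <- M[runs[k, 1], runs[k, 2]] + 1
  M
}

oracle_glrlm_stats <- function(M, np) {
  nr <- sum(M)
  if (nr == 0 || np == 0) return(rep(NA_real_, 11))
  s <- c(SRE = 0, LRE = 0, GLN = 0, RLN = 0, RP = 0, LGRE = 0, HGRE = 0,
         SRLGE = 0, SRHGE = 0, LRLGE = 0, LRHGE = 0)
  for (i in seq_len(nrow(M))) for (l in seq_len(ncol(M))) {
    r <- M[i, l]
    if (r == 0) next
    s["SRE"] <- s["SRE"] + r / l^2;   s["LRE"] <- s["LRE"] + r * l^2
    s["LGRE"] <- s["LGRE"] + r / i^2; s["HGRE"] <- s["HGRE"] + r * i^2
    s["SRLGE"] <- s["SRLGE"] + r / (i^2 * l^2)
    s["SRHGE"] <- s["SRHGE"] + r * i^2 / l^2
    s["LRLGE"] <- s["LRLGE"] + r * l^2 / i^2
    s["LRHGE"] <- s["LRHGE"] + r * i^2 * l^2
  }
  s["GLN"] <- sum(rowSums(M)^2); s["RLN"] <- sum(colSums(M)^2)
  out <- s / nr
  out["RP"] <- nr / np
  out
}

oracle_glrlm_features <- function(levels, dirs = c(0, 45, 90, 135)) {
  np <- sum(!is.na(levels))
  per <- sapply(dirs, function(th)
    oracle_glrlm_stats(oracle_glrlm_runs(levels, th), np))
  rownames(per) <- c("SRE", "LRE", "GLN", "RLN", "RP", "LGRE", "HGRE",
                     "SRLGE", "SRHGE", "LRLGE", "LRHGE")
  apply(per, 1, function(v) { v <- v[is.finite(v)]; if (length(v)) mean(v) else NA_real_ })
}

# ---- AUC oracle: concordant-pair counting ---------------------------------

oracle_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# ---- fixtures -------------------------------------------------------------

random_masked_slice <- function(n = 8, Ng = 4, p_mask = 0.8, seed = 1) {
  set.seed(seed)
  slice <- matrix(runif(n * n), n, n)
  mask <- matrix(runif(n * n) < p_mask, n, n)
  if (!any(mask)) mask[1, 1] <- TRUE
  list(slice = slice, mask = mask, q = quantize(slice, mask, Ng = Ng))
}

tiny_volume <- function(shape = c(12, 12, 6), seed = 1, constant = FALSE) {
  set.seed(seed)
  x <- array(if (constant) 1 else runif(prod(shape)), shape)
  m <- array(1L, shape)
  volume_with_mask(x, m, subject_id = paste0("T", seed))
}

# small synthetic feature table: `informative` columns shifted by `delta`
synthetic_table <- function(n_per_class = 25, p = 20, informative = 1,
                            delta = 2, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(0:1, each = n_per_class)
  M <- matrix(rnorm(n * p), n, p)
  if (informative > 0)
    M[labels == 1, seq_len(informative)] <-
      M[labels == 1, seq_len(informative)] + delta
  ids <- sprintf("S%03d", 1:n)
  ci <- data.frame(name = sprintf("F%03d", 1:p), sequence = "SEQ",
                   tissue = "ROI", feature = sprintf("F%03d", 1:p),
                   stringsAsFactors = FALSE)
  feature_table(M, ids, ci, labels)
}
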