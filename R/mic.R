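# Maximal information coefficient: maximal normalized mutual information
# over grid partitions with grid area bounded by B(n) = n^exponent. One axis
# is equipartitioned; the other partition is optimised by dynamic
# programming over clump boundaries (with superclump coarsening to bound the
# DP size); both orientations are tried and the maximum taken.

# equal-frequency bins that keep tied values together
mic_equipartition <- function(y, nbins) {
  n <- length(y)
  r <- rank(y, ties.method = "first")
  b <- ceiling(r * nbins / n)
  b <- stats::ave(b, y, FUN = function(v) round(mean(v)))
  match(b, sort(unique(b)))          # relabel 1..actual
}

# clump boundaries of q (y-bin labels) in x order; equal-x runs are atomic
mic_clumps <- function(xs, qs) {
  n <- length(xs)
  xg <- cumsum(c(1L, as.integer(xs[-1] != xs[-n])))
  ng <- xg[n]
  pure <- vapply(split(qs, xg), function(v)
    if (length(unique(v)) == 1L) v[1] else -1L, numeric(1))
  cl <- integer(ng)
  cl[1] <- 1L
  for (g in seq_len(ng)[-1]) {
    new_cl <- pure[g] == -1 || pure[g - 1] == -1 || pure[g] != pure[g - 1]
    cl[g] <- cl[g - 1] + as.integer(new_cl)
  }
  cl[xg]                              # clump id per point (in x order)
}

# best I(P;Q) for 2..lmax x-bins, DP over (super)clump boundaries
mic_dp <- function(cl, qs, nya, lmax, cmax) {
  n <- length(cl)
  k <- max(cl)
  # cumulative counts per y-bin at clump right edges (row 1 = zero boundary)
  cnt <- cumsum(tabulate(cl, k))
  cumq <- apply(vapply(seq_len(nya), function(q)
    cumsum(tabulate(cl[qs == q], k)), numeric(k)), 2L, identity)
  cumq <- rbind(0, matrix(cumq, k, nya))
  cnt <- c(0, cnt)
  # superclumps: coarsen boundaries if the DP would be too large
  ksc <- cmax * lmax
  if (k > ksc) {
    targets <- seq_len(ksc) * n / ksc
    keep <- unique(vapply(targets, function(tg)
      which.min(abs(cnt[-1] - tg)), integer(1)))
    keep <- sort(unique(c(keep, k)))
    cumq <- cumq[c(1L, keep + 1L), , drop = FALSE]
    cnt <- cnt[c(1L, keep + 1L)]
    k <- length(keep)
  }
  lg <- function(v) ifelse(v > 0, log2(v), 0)
  # cost of one x-bin spanning boundaries (s, t]: m * H(Q | bin)
  costs_to <- function(t) {           # vector over s = 0..t-1
    mq <- sweep(cumq[seq_len(t), , drop = FALSE], 2L, cumq[t + 1L, ], "-")
    mq <- -mq
    m <- cnt[t + 1L] - cnt[seq_len(t)]
    rowSums(mq * (lg(m) - lg(mq)))
  }
  D <- matrix(Inf, k, lmax)
  for (t in seq_len(k)) D[t, 1] <- costs_to(t)[1]
  if (lmax >= 2L && k >= 2L) {
    for (t in 2:k) {
      ct <- costs_to(t)
      for (l in 2:min(lmax, t)) {
        s <- (l - 1):(t - 1)
        D[t, l] <- min(D[s, l - 1] + ct[s + 1L])
      }
    }
  }
  pq <- tabulate(qs, nya) / n
  hq <- -sum(pq * lg(pq))
  I <- hq - D[k, ] / n                # per l = 1..lmax
  I
}

#' Maximal information coefficient of two samples
#'
#' @param x,y numeric vectors of equal length `n >= 4`.
#' @param exponent grid-size exponent: the grid area is bounded by
#'   `B(n) = n^exponent` (default 0.6).
#' @param cmax superclump factor bounding the dynamic program (default 15).
#' @return MIC in `[0, 1]`; 0 when either sample is constant.
#' @export
mic_score <- function(x, y, exponent = 0.6, cmax = 15L) {
  n <- length(x)
  if (length(y) != n || n < 4L)
    rt_error("x and y must have equal length >= 4", "radtex_invalid_input")
  if (!(exponent > 0 && exponent < 1))
    rt_error("exponent must be in (0, 1)", "radtex_invalid_config")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  B <- max(4, floor(n^exponent))
  best <- 0
  for (orient in 1:2) {
    a <- if (orient == 1L) x else y
    b <- if (orient == 1L) y else x
    o <- order(a, b)
    as <- a[o]; bs <- b[o]
    seen <- character(0)
    for (ny in 2:max(2L, floor(B / 2))) {
      lmax <- floor(B / ny)
      if (lmax < 2L) break
      qs <- mic_equipartition(bs, ny)
      nya <- max(qs)
      if (nya < 2L) next
      # an equipartition realised before (fewer distinct values than bins)
      # was already scanned with a larger or equal lmax -- skip the repeat
      sig <- paste(cumsum(tabulate(qs, nya)), collapse = ",")
      if (sig %in% seen) next
      seen <- c(seen, sig)
      cl <- mic_clumps(as, qs)
      I <- mic_dp(cl, qs, nya, lmax, cmax)
      l <- seq_along(I)
      val <- I / log2(pmin(l, nya))
      val <- val[l >= 2L]
      best <- max(best, val, na.rm = TRUE)
    }
  }
  min(1, max(0, best))
}
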