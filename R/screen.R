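# Univariate discriminative screening: Mann-Whitney U per feature with
# Holm-Bonferroni family-wise error control.

#' Mann-Whitney U test
#'
#' Reports `U` for `x` (number of pairs with `x_i > y_j`, ties counted 1/2).
#' The two-sided p-value is exact (via the null Wilcoxon distribution) when
#' the combined sample size is at most `exact_max` and there are no ties,
#' otherwise a normal approximation with tie correction and continuity
#' correction is used.
#'
#' @param x,y numeric samples (each non-empty).
#' @param exact_max combined-size cutoff for the exact p-value (default 12).
#' @return list with `U` and `p`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12L) {
  if (length(x) < 1L || length(y) < 1L)
    rt_error("empty sample", "radtex_invalid_input")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1L)
  if (N <= exact_max && !has_ties) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 1 - stats::pwilcox(U - 1, n1, n2))
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- U - mu
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)   # continuity correction
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U, p = p)
}

#' Holm-Bonferroni step-down correction
#'
#' Sorts p-values ascending and rejects `p_(k)` while
#' `p_(k) <= alpha / (m - k + 1)`; adjusted p-values are the running maximum
#' of `(m - k + 1) * p_(k)` capped at 1, mapped back to input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param alpha family-wise significance level (default 0.05).
#' @return list with logical `reject` and numeric `adjusted`.
#' @export
holm_bonferroni <- function(pvals, alpha = 0.05) {
  if (any(!is.finite(pvals) | pvals < 0 | pvals > 1))
    rt_error("p-values must lie in [0, 1]", "radtex_invalid_input")
  m <- length(pvals)
  o <- order(pvals)
  sorted <- pvals[o]
  mult <- m - seq_len(m) + 1
  adj_sorted <- pmin(1, cummax(mult * sorted))
  rej_sorted <- logical(m)
  ok <- sorted <= alpha / mult
  if (all(ok)) rej_sorted[] <- TRUE
  else if (any(!ok)) {
    first_fail <- which(!ok)[1]
    if (first_fail > 1L) rej_sorted[seq_len(first_fail - 1L)] <- TRUE
  }
  reject <- logical(m); adjusted <- numeric(m)
  reject[o] <- rej_sorted
  adjusted[o] <- adj_sorted
  list(reject = reject, adjusted = adjusted)
}

#' Screen every feature of a table with Mann-Whitney U + Holm correction
#'
#' Tests each column against the binary labels (`x` = label-1 group). The
#' Holm correction family is, by default, the features of each
#' (sequence, tissue) dataset separately; `family = "pooled"` corrects over
#' all columns jointly.
#'
#' @param t a cleaned [feature_table()].
#' @param alpha significance level (default 0.05).
#' @param family "per_dataset" or "pooled".
#' @return object of class `screen_result`: `per_feature` data.frame
#'   (name, sequence, tissue, U, p, p_adjusted, significant_raw,
#'   significant_holm) and `summary` data.frame of before/after counts per
#'   (sequence, tissue).
#' @export
screen_table <- function(t, alpha = 0.05, family = c("per_dataset", "pooled")) {
  family <- match.arg(family)
  if (length(unique(t$labels)) < 2L)
    rt_error("both classes required for screening", "radtex_invalid_input")
  g1 <- t$labels == 1L
  res <- apply(t$matrix, 2L, function(v) {
    r <- mann_whitney_u(v[g1], v[!g1])
    c(r$U, r$p)
  })
  pf <- data.frame(name = t$col_info$name, sequence = t$col_info$sequence,
                   tissue = t$col_info$tissue,
                   U = res[1, ], p = res[2, ], stringsAsFactors = FALSE,
                   row.names = NULL)
  grp <- if (family == "pooled") rep("all", nrow(pf))
         else paste(pf$sequence, pf$tissue, sep = "|")
  pf$p_adjusted <- NA_real_
  pf$significant_holm <- NA
  for (g in unique(grp)) {
    i <- grp == g
    h <- holm_bonferroni(pf$p[i], alpha)
    pf$p_adjusted[i] <- h$adjusted
    pf$significant_holm[i] <- h$reject
  }
  pf$significant_raw <- pf$p < alpha
  agg <- stats::aggregate(cbind(before = pf$significant_raw,
                                after = pf$significant_holm),
                          by = list(sequence = pf$sequence,
                                    tissue = pf$tissue), FUN = sum)
  structure(list(per_feature = pf, summary = agg, alpha = alpha,
                 m = nrow(pf), family = family),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result:", x$m, "features, alpha =", x$alpha,
      ", family =", x$family, "\n")
  print(x$summary)
  invisible(x)
}
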