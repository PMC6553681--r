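test_that("small-sample exact U test matches rank-assignment enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 2 / 6)
  # identical multisets: U = |x||y|/2 by symmetry
  expect_equal(mann_whitney_u(c(5, 7, 9), c(5, 7, 9))$U, 4.5)
  # enumeration oracle: all C(6,3) label assignments of a fixed pooled sample
  pool <- c(0.3, 0.9, 1.7, 2.2, 3.1, 4.8)
  u_obs <- mann_whitney_u(pool[c(1, 2, 6)], pool[c(3, 4, 5)])$U
  combs <- combn(6, 3)
  us <- apply(combs, 2, function(i)
    sum(outer(pool[i], pool[-i], ">")) + 0.5 * sum(outer(pool[i], pool[-i], "==")))
  p_oracle <- mean(us <= u_obs | us >= (9 - u_obs))
  expect_equal(mann_whitney_u(pool[c(1, 2, 6)], pool[c(3, 4, 5)])$p, p_oracle)
})

test_that("U statistic is invariant under monotone transforms of both samples", {
  set.seed(61)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  base <- mann_whitney_u(x, y)
  tf <- function(v) exp(v) + v^3
  expect_equal(mann_whitney_u(tf(x), tf(y)), base)
})

test_that("large-sample approximation is close to the exact distribution", {
  set.seed(62)
  x <- rnorm(30); y <- rnorm(30)
  ours <- mann_whitney_u(x, y)
  ref <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE,
                                             exact = FALSE))
  expect_equal(ours$U, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
})

test_that("type-I error of the U test is calibrated at alpha = 0.05", {
  set.seed(63)
  reps <- 1000
  rej <- 0L
  for (r in seq_len(reps)) {
    p <- mann_whitney_u(rnorm(50), rnorm(50))$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.035)
  expect_lte(rej / reps, 0.065)
})

test_that("Holm step-down follows the sequential thresholds", {
  expect_equal(holm_bonferroni(c(0.001, 0.01, 0.04), 0.05)$reject,
               rep(TRUE, 3))
  expect_equal(holm_bonferroni(c(0.04, 0.04, 0.04), 0.05)$reject,
               rep(FALSE, 3))
  expect_true(holm_bonferroni(0.04, 0.05)$reject)
  expect_error(holm_bonferroni(c(0.5, 1.2)), class = "radtex_invalid_input")
  # adjusted p-values agree with the reference implementation, in any order
  set.seed(64)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(holm_bonferroni(p)$adjusted, p.adjust(p, "holm"))
  }
})

test_that("Holm sits between Bonferroni and uncorrected on every input", {
  set.seed(65)
  for (i in 1:50) {
    p <- runif(sample(2:40, 1), 0, 0.2)
    m <- length(p)
    holm <- holm_bonferroni(p, 0.05)$reject
    bonf <- p <= 0.05 / m
    raw <- p < 0.05
    expect_true(all(holm[bonf]))        # superset of Bonferroni
    expect_true(all(raw[holm]))         # subset of uncorrected
  }
})

test_that("screen_table tabulates before/after counts and flags injections", {
  t1 <- synthetic_table(n_per_class = 25, p = 30, informative = 1,
                        delta = 3, seed = 66)
  sr <- screen_table(t1)
  expect_equal(sr$m, 30)
  expect_true(sr$per_feature$significant_holm[1])
  expect_gte(sum(sr$per_feature$significant_raw),
             sum(sr$per_feature$significant_holm))
  expect_true(all(sr$per_feature$p >= 0 & sr$per_feature$p <= 1))
  # duplicating every row per group preserves the ordering invariant
  t2 <- t1
  t2$matrix <- rbind(t1$matrix, t1$matrix)
  t2$row_ids <- c(t1$row_ids, paste0(t1$row_ids, "b"))
  t2$labels <- c(t1$labels, t1$labels)
  rownames(t2$matrix) <- t2$row_ids
  sr2 <- screen_table(t2)
  expect_gte(sum(sr2$per_feature$significant_raw),
             sum(sr2$per_feature$significant_holm))
  expect_error(screen_table(radtex:::subset_rows(t1, 1:25)),
               class = "radtex_invalid_input")
})

test_that("pooled and per-dataset families differ only in the correction", {
  t1 <- synthetic_table(n_per_class = 20, p = 10, seed = 67)
  a <- screen_table(t1, family = "per_dataset")
  b <- screen_table(t1, family = "pooled")
  expect_equal(a$per_feature$p, b$per_feature$p)
})
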