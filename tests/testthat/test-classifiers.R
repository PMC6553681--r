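sep_data <- function(n = 40, p = 4, delta = 3, seed = 81) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1] <- X[y == 1, 1] + delta
  list(X = X, y = y)
}

test_that("linear SVM separates separable data and is deterministic", {
  d <- sep_data()
  f1 <- svm_linear(d$X, d$y, C = 1, seed = 5)
  f2 <- svm_linear(d$X, d$y, C = 1, seed = 5)
  expect_identical(f1$w, f2$w)
  expect_equal(roc_auc(predict(f1, d$X), d$y), 1)
  # the class-1 direction dominates the weight vector
  expect_gt(abs(f1$w[1]), max(abs(f1$w[-1])))
  expect_error(svm_linear(d$X, rep(1L, 40)), class = "radtex_degenerate_fold")
})

test_that("SVM margin shrinks training-error trade-off with C as expected", {
  set.seed(82)
  y <- rep(0:1, each = 30)
  X <- matrix(rnorm(60 * 2), 60, 2)
  X[y == 1, 1] <- X[y == 1, 1] + 1.2     # overlapping classes
  w_small <- svm_linear(X, y, C = 2^-3, seed = 1)
  w_large <- svm_linear(X, y, C = 2^3, seed = 1)
  expect_lt(sqrt(sum(w_small$w^2)), sqrt(sum(w_large$w^2)))
})

test_that("random forest scores are vote fractions, deterministic by seed", {
  d <- sep_data(n = 60)
  s1 <- rf_score(d$X, d$y, d$X, mtry = 2, ntree = 100, seed = 9)
  s2 <- rf_score(d$X, d$y, d$X, mtry = 2, ntree = 100, seed = 9)
  s3 <- rf_score(d$X, d$y, d$X, mtry = 2, ntree = 100, seed = 10)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_gte(roc_auc(s1, d$y), 0.99)     # near-perfect resubstitution
})

test_that("random forest generalises on held-out separable data", {
  d <- sep_data(n = 60, seed = 83)
  h <- sep_data(n = 40, seed = 84)
  s <- rf_score(d$X, d$y, h$X, mtry = 2, ntree = 250, seed = 11)
  expect_gte(roc_auc(s, h$y), 0.95)
})

test_that("forests are insensitive to duplicated pure-noise features", {
  d <- sep_data(n = 60, p = 2, seed = 85)
  Xn <- cbind(d$X, matrix(rnorm(60 * 10), 60, 10))
  h <- sep_data(n = 30, p = 2, seed = 86)
  Hn <- cbind(h$X, matrix(rnorm(30 * 10), 30, 10))
  s <- rf_score(Xn, d$y, Hn, mtry = 4, ntree = 250, seed = 12)
  expect_gte(roc_auc(s, h$y), 0.9)
})
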