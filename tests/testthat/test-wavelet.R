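test_that("orthonormal Haar on a constant block", {
  d <- haar_decompose(matrix(1, 2, 2), 1)
  expect_equal(c(d$subbands$LL1), 2)
  expect_equal(c(d$subbands$LH1), 0)
  expect_equal(c(d$subbands$HL1), 0)
  expect_equal(c(d$subbands$HH1), 0)
})

test_that("level-1 energy conservation and perfect reconstruction", {
  set.seed(11)
  for (n in c(4, 8, 16)) {
    x <- matrix(rnorm(n * n), n, n)
    d <- haar_decompose(x, 1)
    e1 <- sum(vapply(d$subbands, function(s) sum(s^2), numeric(1)))
    expect_equal(e1, sum(x^2), tolerance = 1e-9)
    expect_equal(haar_reconstruct(d, 1), x, tolerance = 1e-9)
  }
})

test_that("odd sizes pad by edge replication and reconstruct the padded input", {
  set.seed(12)
  x <- matrix(rnorm(35), 5, 7)
  d <- haar_decompose(x, 1)
  rec <- haar_reconstruct(d, 1)
  expect_equal(dim(rec), c(6L, 8L))
  expect_equal(rec[1:5, 1:7], x, tolerance = 1e-9)
  expect_equal(rec[6, 1:7], x[5, ], tolerance = 1e-9)
})

test_that("decomposition stops early below 2x2 and is flagged", {
  d <- haar_decompose(matrix(rnorm(4), 2, 2), 3)
  expect_true(d$early_stop)
  expect_equal(d$levels_done, 1L)
  expect_error(haar_reconstruct(d, 2), class = "radtex_invalid_input")
})

test_that("WSF: constant image, scaling law, and fixed arity", {
  f <- wsf_features(matrix(1, 16, 16), matrix(TRUE, 16, 16))
  expect_length(f, 26)
  expect_equal(unname(f["Mean_OI"]), 1)
  expect_equal(unname(f["SD_OI"]), 0)
  expect_equal(unname(f["Mean_HH1"]), 0)

  set.seed(13)
  sl <- matrix(runif(256), 16, 16); mk <- matrix(TRUE, 16, 16)
  f1 <- wsf_features(sl, mk)
  f3 <- wsf_features(3 * sl, mk)
  means <- grepl("^Mean", names(f1))
  expect_equal(unname(f3[means]), unname(3 * f1[means]), tolerance = 1e-12)
  expect_equal(unname(f3[!means]), unname(3 * f1[!means]), tolerance = 1e-12)
})

test_that("WSF: mask too small for 3 levels leaves deep subbands NA", {
  mk <- matrix(FALSE, 16, 16); mk[1:3, 1:3] <- TRUE   # 3x3 crop: 1 level only
  f <- wsf_features(matrix(runif(256), 16, 16), mk)
  expect_length(f, 26)
  expect_true(all(is.finite(f[c("Mean_OI", "SD_OI", "Mean_LL1")])))
  expect_true(all(is.na(f[c("Mean_LL3", "SD_HH3")])))
})

test_that("WCF: constant image degenerates as a single-cell GLCM; arity 24", {
  f <- wcf_features(matrix(2, 16, 16), matrix(TRUE, 16, 16))
  expect_length(f, 24)
  expect_equal(unname(f["Energy_HH1"]), 1)
  expect_equal(unname(f["Contrast_HH1"]), 0)
  expect_true(is.na(f["Correlation_HH1"]))
})

test_that("WCF LL1 statistics equal the GLCM oracle on the quantized subband", {
  set.seed(14)
  sl <- matrix(runif(64), 8, 8); mk <- matrix(TRUE, 8, 8)
  cfg <- texture_config()
  got <- wcf_features(sl, mk, cfg)
  ll1 <- haar_decompose(sl, 1)$subbands$LL1
  q <- quantize(ll1, matrix(TRUE, nrow(ll1), ncol(ll1)), Ng = cfg$Ng)
  want <- oracle_glcm_features(q$levels)
  for (st in c("Energy", "Contrast", "Correlation", "Homogeneity",
               "Entropy", "Variance"))
    expect_equal(unname(got[paste0(st, "_LL1")]), unname(want[st]),
                 tolerance = 1e-10, label = st)
})
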