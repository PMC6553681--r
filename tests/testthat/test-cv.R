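test_that("stratified folds partition samples with balanced classes", {
  labels <- rep(0:1, each = 50)
  plan <- cv_plan(k = 5, R = 10, base_seed = 3)
  folds <- make_folds(labels, plan)
  expect_length(folds, 50)
  for (r in 1:10) {
    fr <- folds[(5 * r - 4):(5 * r)]
    tests <- lapply(fr, `[[`, "test")
    expect_equal(sort(unlist(tests)), 1:100)          # partition law
    expect_equal(max(table(unlist(tests))), 1L)       # pairwise disjoint
    for (fd in fr) {
      expect_equal(length(fd$test), 20L)
      expect_equal(sum(labels[fd$test] == 1L), 10L)
      expect_equal(sort(c(fd$train, fd$test)), 1:100)
    }
  }
  # determinism
  expect_identical(folds, make_folds(labels, plan))
  # tiny balanced case
  f2 <- make_folds(c(0, 0, 1, 1), cv_plan(k = 2, R = 1, base_seed = 1))
  expect_equal(lengths(lapply(f2, `[[`, "test")), c(2L, 2L))
  expect_error(make_folds(c(0, 1, 1, 1), cv_plan(k = 2, R = 1)),
               class = "radtex_invalid_input")
})

test_that("roc_auc equals concordant-pair counting on exhaustive small inputs", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4), c(1, 0)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_true(is.na(roc_auc(1:4, rep(1, 4))))
  set.seed(91)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    sc <- sample(1:4, n, replace = TRUE)       # ties likely
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(sc, lb), oracle_auc(sc, lb))
  }
})

test_that("rankings find injected signal and never touch test rows", {
  t1 <- synthetic_table(n_per_class = 25, p = 15, informative = 1,
                        delta = 3, seed = 92)
  for (mth in c("pvalue", "mic")) {
    rk <- rank_features(t1, ranking_config(mth))
    expect_equal(rk[1], "F001")
    expect_setequal(rk, colnames(t1$matrix))
  }
  # leakage check: mutating rows outside the training table cannot matter
  tr <- radtex:::subset_rows(t1, 1:40)
  expect_identical(rank_features(tr, ranking_config("pvalue")),
                   rank_features(tr, ranking_config("pvalue")))
  expect_error(rank_features(radtex:::subset_rows(t1, 1:25)),
               class = "radtex_invalid_input")
})

test_that("evaluate produces 50 iterations per configuration at defaults", {
  t1 <- synthetic_table(n_per_class = 25, p = 8, delta = 2.5, seed = 93)
  res <- evaluate(t1, model_grid(svm_C = c(0.5, 1), rf_mtry = 2,
                                 rf_ntree = 50), cv_plan(k = 5, R = 10,
                                                         base_seed = 4))
  expect_equal(nrow(res$metrics), 3L)
  expect_equal(unique(res$metrics$n_iter), 50)
  expect_equal(ncol(res$aucs), 50L)
  expect_true(all(res$aucs >= 0 & res$aucs <= 1, na.rm = TRUE))
  # every sample is tested exactly R times
  expect_true(all(res$per_sample$tested == 10L))
  # determinism of the full result
  res2 <- evaluate(t1, model_grid(svm_C = c(0.5, 1), rf_mtry = 2,
                                  rf_ntree = 50), cv_plan(k = 5, R = 10,
                                                          base_seed = 4))
  expect_identical(res$aucs, res2$aucs)
})

test_that("separable data is recovered; permuted labels are not", {
  t1 <- synthetic_table(n_per_class = 25, p = 8, delta = 3, seed = 94)
  plan <- cv_plan(k = 5, R = 2, base_seed = 5)
  grid <- model_grid(svm_C = 1, rf_mtry = 2, rf_ntree = 100)
  res <- evaluate(t1, grid, plan)
  expect_gte(res$best$svm$mean_auc, 0.95)
  expect_gte(res$best$rf$mean_auc, 0.95)
  set.seed(95)
  tp <- t1
  tp$labels <- sample(tp$labels)
  resp <- evaluate(tp, grid, plan)
  expect_lt(resp$best$svm$mean_auc, 0.72)
  expect_gt(resp$best$svm$mean_auc, 0.28)
})

test_that("no leakage: mutating test-fold values leaves the iteration's fit alone", {
  t1 <- synthetic_table(n_per_class = 10, p = 5, seed = 96)
  plan <- cv_plan(k = 5, R = 1, base_seed = 6)
  folds <- make_folds(t1$labels, plan)
  fd <- folds[[1]]
  tr <- radtex:::subset_rows(t1, fd$train)
  te <- radtex:::subset_rows(t1, fd$test)
  te_mut <- te; te_mut$matrix <- te$matrix * 13 - 5
  s1 <- standardize(tr, te)
  s2 <- standardize(tr, te_mut)
  expect_identical(s1$center, s2$center)
  expect_identical(s1$scale, s2$scale)
  expect_identical(rank_features(s1$train, ranking_config("mic")),
                   rank_features(s2$train, ranking_config("mic")))
  f1 <- svm_linear(s1$train$matrix, tr$labels, C = 1, seed = 7)
  f2 <- svm_linear(s2$train$matrix, tr$labels, C = 1, seed = 7)
  expect_identical(f1$w, f2$w)
})

test_that("selection sweep: argmax is small with one informative feature and
           the full-size point matches evaluate without selection", {
  t1 <- synthetic_table(n_per_class = 25, p = 12, informative = 1,
                        delta = 2.5, seed = 97)
  plan <- cv_plan(k = 5, R = 2, base_seed = 8)
  grid <- model_grid(svm_C = 1, rf_mtry = 2, rf_ntree = 50)
  sw <- selection_sweep(t1, grid, plan, ranking_config("mic"),
                        top_ks = c(1, 2, 6, 12), models = "svm")
  expect_equal(nrow(sw$profile), 4L)
  full <- sw$profile$mean_auc[sw$profile$top_k == 12]
  res <- evaluate(t1, grid, plan, models = "svm")
  expect_equal(full, res$best$svm$mean_auc, tolerance = 1e-12)
})

test_that("per-sample consistency proportions and the intersection law", {
  t1 <- synthetic_table(n_per_class = 15, p = 6, delta = 3, seed = 98)
  res <- evaluate(t1, model_grid(svm_C = 1, rf_mtry = 2, rf_ntree = 50),
                  cv_plan(k = 5, R = 4, base_seed = 9))
  ca <- sample_consistency(res, "svm")
  cb <- sample_consistency(res, "rf")
  expect_true(all(ca$tested == 4L))
  expect_true(all(ca$proportion >= 0 & ca$proportion <= 1))
  both <- consistency_intersection(ca, cb)
  expect_true(all(ca$consistent[both]))
  expect_true(all(cb$consistent[both]))
  # most samples are consistently correct; the few that sit on the wrong
  # side of the class overlap are consistently wrong, not borderline
  expect_gte(mean(ca$consistent), 0.7)
  expect_true(all(ca$correct <= ca$tested))
})

test_that("bootstrap_pearson: exact cases, determinism and degenerate input", {
  x <- 1:10
  bp <- bootstrap_pearson(x, 2 * x + 1, B = 200, seed = 1)
  expect_equal(bp$r, 1)
  expect_equal(unname(bp$ci), c(1, 1))
  expect_equal(bootstrap_pearson(c(1, 2, 3), c(1, 3, 2), B = 100, seed = 2)$r,
               0.5)
  b1 <- bootstrap_pearson(rnorm(20), rnorm(20), B = 100, seed = 3)
  expect_error(bootstrap_pearson(rep(1, 10), 1:10, B = 100, seed = 4),
               class = "radtex_invalid_input")
  set.seed(99)
  x <- rnorm(30); y <- rnorm(30)
  expect_identical(bootstrap_pearson(x, y, B = 300, seed = 5),
                   bootstrap_pearson(x, y, B = 300, seed = 5))
})

test_that("upfront standardization mode reproduces rankings but not fold fits", {
  t1 <- synthetic_table(n_per_class = 15, p = 6, delta = 2, seed = 301)
  plan <- cv_plan(k = 5, R = 2, base_seed = 30)
  grid <- model_grid(svm_C = 1, rf_mtry = 2, rf_ntree = 50)
  a <- evaluate(t1, grid, plan, standardize_mode = "fold")
  b <- evaluate(t1, grid, plan, standardize_mode = "upfront")
  expect_equal(dim(a$aucs), dim(b$aucs))
  # both modes see the same separable signal
  expect_gte(b$best$svm$mean_auc, 0.9)
})

test_that("nested evaluation selects hyperparameters without the reported folds", {
  t1 <- synthetic_table(n_per_class = 15, p = 6, delta = 2.5, seed = 302)
  res <- evaluate_nested(t1, model_grid(svm_C = c(0.25, 4), rf_mtry = c(2L, 4L),
                                        rf_ntree = 50L),
                         cv_plan(k = 5, R = 1, base_seed = 31))
  expect_equal(res$metrics$n_iter, c(5, 5))
  expect_true(all(res$chosen["svm", ] %in% c(0.25, 4)))
  expect_true(all(res$chosen["rf", ] %in% c(2, 4)))
  expect_gte(res$metrics$mean_auc[res$metrics$model == "svm"], 0.85)
})
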