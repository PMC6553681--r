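# Repeated stratified k-fold cross-validation over SVM-C and RF-mtry tuning
# grids, with optional fold-internal filter feature selection, averaged AUC
# (mean +/- SD over the k*R iterations), per-sample consistency tallies, and
# bootstrapped Pearson correlation against external covariates.

#' Classifier tuning grids
#'
#' @param svm_C SVM cost grid (default `2^(-3:3)`).
#' @param rf_mtry random-forest variables-per-split grid
#'   (default `c(2, 4, 6, 8, 10, 12)`).
#' @param rf_ntree trees per forest (default 250).
#' @return object of class `model_grid`.
#' @export
model_grid <- function(svm_C = 2^(-3:3), rf_mtry = c(2L, 4L, 6L, 8L, 10L, 12L),
                       rf_ntree = 250L) {
  if (length(svm_C) < 1L || length(rf_mtry) < 1L || rf_ntree < 1L)
    rt_error("grids must be non-empty and ntree >= 1", "radtex_invalid_config")
  structure(list(svm_C = svm_C, rf_mtry = as.integer(rf_mtry),
                 rf_ntree = as.integer(rf_ntree)), class = "model_grid")
}

#' Cross-validation plan
#'
#' @param k folds (default 5).
#' @param R repetitions (default 10).
#' @param base_seed integer seed; repetition `r` shuffles with
#'   `spawn_seed(base_seed, r)`.
#' @return object of class `cv_plan` (always stratified).
#' @export
cv_plan <- function(k = 5L, R = 10L, base_seed = 1L) {
  k <- as.integer(k); R <- as.integer(R)
  if (k < 2L || R < 1L) rt_error("need k >= 2, R >= 1", "radtex_invalid_config")
  structure(list(k = k, R = R, base_seed = as.integer(base_seed),
                 stratified = TRUE), class = "cv_plan")
}

#' Filter feature-ranking configuration
#'
#' @param method "pvalue" (ascending Mann-Whitney p) or "mic" (descending
#'   maximal information coefficient).
#' @param mic_grid_exponent MIC grid-size exponent in (0, 1), default 0.6.
#' @return object of class `ranking_config`.
#' @export
ranking_config <- function(method = c("pvalue", "mic"),
                           mic_grid_exponent = 0.6) {
  method <- match.arg(method)
  if (!(mic_grid_exponent > 0 && mic_grid_exponent < 1))
    rt_error("mic_grid_exponent must be in (0, 1)", "radtex_invalid_config")
  structure(list(method = method, mic_grid_exponent = mic_grid_exponent),
            class = "ranking_config")
}

#' Stratified repeated k-fold splits
#'
#' Within each repetition the test folds partition all samples and each fold
#' holds every class in proportion within one sample of the global balance.
#' Deterministic given the plan.
#'
#' @param labels integer 0/1 vector.
#' @param plan a [cv_plan()].
#' @return list of `k * R` splits, each a list with `train`, `test`
#'   (integer indices), `rep`, `fold`.
#' @export
make_folds <- function(labels, plan) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (min(table(labels)) < plan$k)
    rt_error("a class has fewer samples than folds", "radtex_invalid_input")
  out <- vector("list", plan$k * plan$R)
  pos <- 0L
  for (r in seq_len(plan$R)) {
    fold_of <- integer(n)
    with_seed(spawn_seed(plan$base_seed, r), {
      for (cl in unique(labels)) {
        idx <- which(labels == cl)
        idx <- idx[sample.int(length(idx))]
        fold_of[idx] <- rep(seq_len(plan$k), length.out = length(idx))
      }
    })
    for (f in seq_len(plan$k)) {
      pos <- pos + 1L
      out[[pos]] <- list(train = which(fold_of != f),
                         test = which(fold_of == f), rep = r, fold = f)
    }
  }
  out
}

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half (equivalent to the trapezoidal ROC area). Returns `NA`
#' with attribute `degenerate = TRUE` when only one class is present.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels integer 0/1.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  np <- sum(labels == 1L); nn <- sum(labels == 0L)
  if (np == 0L || nn == 0L)
    return(structure(NA_real_, degenerate = TRUE))
  r <- rank(scores)
  (sum(r[labels == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Rank features by univariate discriminative power
#'
#' Computed from training rows only. The p-value method sorts ascending raw
#' Mann-Whitney p; the MIC method sorts descending `mic_score(feature,
#' label)`. Ties break by feature name (stable).
#'
#' @param train a [feature_table()] (training rows only).
#' @param cfg a [ranking_config()].
#' @return character vector of feature names, best first.
#' @export
rank_features <- function(train, cfg = ranking_config()) {
  if (length(unique(train$labels)) < 2L)
    rt_error("both classes required for ranking", "radtex_invalid_input")
  nm <- colnames(train$matrix)
  if (cfg$method == "pvalue") {
    g1 <- train$labels == 1L
    key <- apply(train$matrix, 2L, function(v)
      mann_whitney_u(v[g1], v[!g1])$p)
    nm[order(key, nm)]
  } else {
    key <- apply(train$matrix, 2L, function(v)
      mic_score(v, train$labels, exponent = cfg$mic_grid_exponent))
    nm[order(-key, nm)]
  }
}

# drop columns that are constant within a training fold (they carry no
# information for that iteration and would break standardization)
drop_fold_constant <- function(tr, te) {
  keep <- apply(tr$matrix, 2L, stats::sd) > 0
  if (!any(keep)) rt_error("all columns constant in fold", "radtex_degenerate_fold")
  list(tr = subset_cols(tr, keep), te = subset_cols(te, keep))
}

subset_cols <- function(t, keep) {
  feature_table(t$matrix[, keep, drop = FALSE], t$row_ids,
                t$col_info[keep, , drop = FALSE], t$labels,
                t$provenance[keep])
}

# metrics of one scored test fold at the native threshold
fold_metrics <- function(scores, labels, threshold) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L); fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L); fp <- sum(pred == 1L & labels == 0L)
  c(auc = as.numeric(roc_auc(scores, labels)),
    sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    acc = (tp + tn) / length(labels))
}

#' Evaluate classifiers with repeated stratified cross-validation
#'
#' For every hyperparameter of the requested models: train on k-1 folds,
#' score the held-out fold with continuous scores, and report the AUC (and
#' sensitivity/specificity/accuracy at the native threshold) averaged over
#' the `k * R` iterations. Standardization -- and, when `selection` is given,
#' the feature ranking -- is fit inside each training fold; test rows never
#' influence it. Degenerate iterations (a training fold missing a class) are
#' flagged and excluded, never imputed.
#'
#' @param table a cleaned [feature_table()].
#' @param grid a [model_grid()].
#' @param plan a [cv_plan()].
#' @param selection optional list `list(cfg = ranking_config(), top_k = n)`:
#'   keep the `top_k` best-ranked features of each training fold (applied in
#'   original column order, so `top_k = ncol` reproduces no selection).
#' @param models character subset of `c("svm", "rf")`.
#' @param standardize_mode "fold" (default, leakage-safe: means/SDs fit on
#'   each training fold) or "upfront" (standardize the full table once
#'   before splitting, as study pipelines that standardize before
#'   cross-validation do; mild optimism, provided for comparability).
#' @return object of class `cv_result`: `metrics` data.frame (one row per
#'   model x hyperparameter: mean_auc, sd_auc, mean sens/spec/acc, n_iter,
#'   n_failed), `aucs` (config x iteration matrix), `best` (per model),
#'   `per_sample` (per config: times tested / times correct), `selected`
#'   (per-iteration selected features, when selection is active), and the
#'   inputs' plans for provenance.
#' @export
evaluate <- function(table, grid = model_grid(), plan = cv_plan(),
                     selection = NULL, models = c("svm", "rf"),
                     standardize_mode = c("fold", "upfront")) {
  models <- match.arg(models, several.ok = TRUE)
  standardize_mode <- match.arg(standardize_mode)
  if (standardize_mode == "upfront")
    table <- standardize(table)$train
  folds <- make_folds(table$labels, plan)
  ni <- length(folds)
  n <- nrow(table$matrix)
  configs <- data.frame(model = character(0), hyper = numeric(0))
  if ("svm" %in% models)
    configs <- rbind(configs, data.frame(model = "svm", hyper = grid$svm_C))
  if ("rf" %in% models)
    configs <- rbind(configs, data.frame(model = "rf", hyper = grid$rf_mtry))
  nc <- nrow(configs)
  aucs <- matrix(NA_real_, nc, ni)
  sens <- spec <- acc <- matrix(NA_real_, nc, ni)
  tested <- matrix(0L, nc, n)
  correct <- matrix(0L, nc, n)
  selected <- if (is.null(selection)) NULL else vector("list", ni)
  n_failed <- 0L
  for (it in seq_len(ni)) {
    fd <- folds[[it]]
    tr <- subset_rows(table, fd$train)
    te <- subset_rows(table, fd$test)
    if (length(unique(tr$labels)) < 2L) { n_failed <- n_failed + 1L; next }
    fc <- drop_fold_constant(tr, te)
    if (standardize_mode == "fold") {
      std <- standardize(fc$tr, fc$te)
    } else {
      std <- list(train = fc$tr, apply_to = fc$te)
    }
    Xtr <- std$train$matrix; Xte <- std$apply_to$matrix
    if (!is.null(selection)) {
      rk <- rank_features(std$train, selection$cfg)
      keep_set <- utils::head(rk, selection$top_k)
      keep <- colnames(Xtr)[colnames(Xtr) %in% keep_set]
      selected[[it]] <- keep
      Xtr <- Xtr[, keep, drop = FALSE]
      Xte <- Xte[, keep, drop = FALSE]
    }
    seed_it <- spawn_seed(plan$base_seed, 5000L + it)
    for (ci in seq_len(nc)) {
      sc <- if (configs$model[ci] == "svm") {
        fit <- svm_linear(Xtr, tr$labels, C = configs$hyper[ci], seed = seed_it)
        list(scores = predict(fit, Xte), thr = 0)
      } else {
        list(scores = rf_score(Xtr, tr$labels, Xte,
                               mtry = configs$hyper[ci],
                               ntree = grid$rf_ntree, seed = seed_it),
             thr = 0.5)
      }
      m <- fold_metrics(sc$scores, te$labels, sc$thr)
      aucs[ci, it] <- m["auc"]; sens[ci, it] <- m["sens"]
      spec[ci, it] <- m["spec"]; acc[ci, it] <- m["acc"]
      pred <- as.integer(sc$scores > sc$thr)
      tested[ci, fd$test] <- tested[ci, fd$test] + 1L
      correct[ci, fd$test] <- correct[ci, fd$test] +
        as.integer(pred == te$labels)
    }
  }
  metrics <- cbind(configs,
                   mean_auc = rowMeans(aucs, na.rm = TRUE),
                   sd_auc = apply(aucs, 1L, stats::sd, na.rm = TRUE),
                   mean_sens = rowMeans(sens, na.rm = TRUE),
                   mean_spec = rowMeans(spec, na.rm = TRUE),
                   mean_acc = rowMeans(acc, na.rm = TRUE),
                   n_iter = rowSums(!is.na(aucs)),
                   n_failed = n_failed)
  best <- lapply(unique(configs$model), function(md) {
    i <- which(configs$model == md)
    b <- i[which.max(metrics$mean_auc[i])]
    list(model = md, hyper = configs$hyper[b], mean_auc = metrics$mean_auc[b],
         sd_auc = metrics$sd_auc[b], config_index = b)
  })
  names(best) <- unique(configs$model)
  structure(list(metrics = metrics, aucs = aucs, best = best,
                 per_sample = list(tested = tested, correct = correct),
                 selected = selected, row_ids = table$row_ids,
                 labels = table$labels, grid = grid, plan = plan,
                 selection = selection, n_failed = n_failed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", nrow(x$metrics), "configurations x", ncol(x$aucs),
      "iterations (", x$n_failed, "failed )\n")
  for (b in x$best)
    cat(sprintf("  best %s: hyper = %g, AUC = %.3f (SD %.3f)\n",
                b$model, b$hyper, b$mean_auc, b$sd_auc))
  invisible(x)
}

#' Nested ("honest") cross-validated evaluation
#'
#' [evaluate()] reports, per hyperparameter, the same CV estimate that is
#' used to pick the best hyperparameter, which carries a mild selection
#' optimism. This variant removes it: within each outer training fold an
#' inner stratified CV picks the hyperparameter per model, one model per
#' outer iteration is refit on the whole training fold with that choice,
#' and only the outer test folds enter the reported AUC.
#'
#' @param table a cleaned [feature_table()].
#' @param grid a [model_grid()].
#' @param plan outer [cv_plan()].
#' @param models character subset of `c("svm", "rf")`.
#' @param inner_k inner folds for hyperparameter selection (default 3).
#' @return list with `metrics` (per model: mean_auc, sd_auc over outer
#'   iterations) and `chosen` (model x iteration matrix of selected
#'   hyperparameters).
#' @export
evaluate_nested <- function(table, grid = model_grid(), plan = cv_plan(),
                            models = c("svm", "rf"), inner_k = 3L) {
  models <- match.arg(models, several.ok = TRUE)
  folds <- make_folds(table$labels, plan)
  ni <- length(folds)
  aucs <- matrix(NA_real_, length(models), ni,
                 dimnames = list(models, NULL))
  chosen <- matrix(NA_real_, length(models), ni,
                   dimnames = list(models, NULL))
  for (it in seq_len(ni)) {
    fd <- folds[[it]]
    tr <- subset_rows(table, fd$train)
    te <- subset_rows(table, fd$test)
    if (length(unique(tr$labels)) < 2L) next
    inner <- evaluate(tr, grid,
                      cv_plan(inner_k, 1L,
                              base_seed = spawn_seed(plan$base_seed,
                                                     7000L + it)),
                      models = models)
    fc <- drop_fold_constant(tr, te)
    std <- standardize(fc$tr, fc$te)
    seed_it <- spawn_seed(plan$base_seed, 5000L + it)
    for (md in models) {
      hy <- inner$best[[md]]$hyper
      chosen[md, it] <- hy
      sc <- if (md == "svm")
        predict(svm_linear(std$train$matrix, tr$labels, C = hy,
                           seed = seed_it), std$apply_to$matrix)
      else
        rf_score(std$train$matrix, tr$labels, std$apply_to$matrix,
                 mtry = hy, ntree = grid$rf_ntree, seed = seed_it)
      aucs[md, it] <- as.numeric(roc_auc(sc, te$labels))
    }
  }
  metrics <- data.frame(model = models,
                        mean_auc = rowMeans(aucs, na.rm = TRUE),
                        sd_auc = apply(aucs, 1L, stats::sd, na.rm = TRUE),
                        n_iter = rowSums(!is.na(aucs)))
  list(metrics = metrics, chosen = chosen, aucs = aucs)
}

#' Sweep the number of selected features
#'
#' Mean cross-validated AUC for every feature-subset size `top_k` under a
#' fixed ranking method, with the same folds and classifier seeds as
#' [evaluate()] (so the profile at `top_k = ncol` matches no selection).
#'
#' @param table a cleaned [feature_table()].
#' @param grid a [model_grid()].
#' @param plan a [cv_plan()].
#' @param cfg a [ranking_config()].
#' @param top_ks subset sizes to evaluate (default `1:ncol`).
#' @param models classifier subset, as in [evaluate()].
#' @return object of class `selection_sweep`: `profile` data.frame (top_k,
#'   model, mean_auc, sd_auc), `argmax` (per model), and the per-iteration
#'   rankings.
#' @export
selection_sweep <- function(table, grid = model_grid(), plan = cv_plan(),
                            cfg = ranking_config(), top_ks = NULL,
                            models = "svm") {
  m <- ncol(table$matrix)
  if (is.null(top_ks)) top_ks <- seq_len(m)
  folds <- make_folds(table$labels, plan)
  ni <- length(folds)
  # per-iteration standardized matrices and rankings, computed once
  prep <- vector("list", ni)
  for (it in seq_len(ni)) {
    fd <- folds[[it]]
    tr <- subset_rows(table, fd$train)
    te <- subset_rows(table, fd$test)
    if (length(unique(tr$labels)) < 2L) next
    fc <- drop_fold_constant(tr, te)
    std <- standardize(fc$tr, fc$te)
    prep[[it]] <- list(Xtr = std$train$matrix, Xte = std$apply_to$matrix,
                       ytr = tr$labels, yte = te$labels,
                       rank = rank_features(std$train, cfg),
                       seed = spawn_seed(plan$base_seed, 5000L + it))
  }
  rows <- list()
  for (tk in top_ks) {
    for (md in models) {
      hypers <- if (md == "svm") grid$svm_C else grid$rf_mtry
      best_mean <- -Inf; best_sd <- NA_real_; best_h <- NA_real_
      for (h in hypers) {
        a <- rep(NA_real_, ni)
        for (it in seq_len(ni)) {
          pp <- prep[[it]]
          if (is.null(pp)) next
          keep_set <- utils::head(pp$rank, tk)
          keep <- colnames(pp$Xtr)[colnames(pp$Xtr) %in% keep_set]
          sc <- if (md == "svm") {
            predict(svm_linear(pp$Xtr[, keep, drop = FALSE], pp$ytr,
                               C = h, seed = pp$seed),
                    pp$Xte[, keep, drop = FALSE])
          } else {
            rf_score(pp$Xtr[, keep, drop = FALSE], pp$ytr,
                     pp$Xte[, keep, drop = FALSE], mtry = h,
                     ntree = grid$rf_ntree, seed = pp$seed)
          }
          a[it] <- as.numeric(roc_auc(sc, pp$yte))
        }
        mu <- mean(a, na.rm = TRUE)
        if (mu > best_mean) {
          best_mean <- mu; best_sd <- stats::sd(a, na.rm = TRUE); best_h <- h
        }
      }
      rows[[length(rows) + 1L]] <-
        data.frame(top_k = tk, model = md, hyper = best_h,
                   mean_auc = best_mean, sd_auc = best_sd)
    }
  }
  profile <- do.call(rbind, rows)
  argmax <- lapply(unique(profile$model), function(md) {
    pr <- profile[profile$model == md, ]
    b <- pr[which.max(pr$mean_auc), ]
    list(model = md, top_k = b$top_k, mean_auc = b$mean_auc)
  })
  names(argmax) <- unique(profile$model)
  structure(list(profile = profile, argmax = argmax, method = cfg$method),
            class = "selection_sweep")
}

#' Per-sample classification consistency
#'
#' Proportion of test appearances in which each sample was correctly
#' classified under a configuration (default: the model's best
#' hyperparameter), plus, given two results/models, the samples consistently
#' correct (proportion >= `threshold`) under BOTH.
#'
#' @param result a [evaluate()] result.
#' @param model which model's best configuration to read (default first).
#' @param threshold consistency cutoff (default 0.8).
#' @return data.frame with `subject`, `tested`, `correct`, `proportion`,
#'   `consistent` (`NA` proportion when a sample was never tested).
#' @export
sample_consistency <- function(result, model = NULL, threshold = 0.8) {
  if (is.null(model)) model <- names(result$best)[1]
  ci <- result$best[[model]]$config_index
  tested <- result$per_sample$tested[ci, ]
  correct <- result$per_sample$correct[ci, ]
  prop <- ifelse(tested > 0L, correct / tested, NA_real_)
  data.frame(subject = result$row_ids, tested = tested, correct = correct,
             proportion = prop,
             consistent = !is.na(prop) & prop >= threshold)
}

#' Samples consistently correct under both classifiers
#'
#' @param cons_a,cons_b two [sample_consistency()] data.frames on the same
#'   subjects.
#' @return logical vector: consistent under both.
#' @export
consistency_intersection <- function(cons_a, cons_b) {
  stopifnot(identical(cons_a$subject, cons_b$subject))
  cons_a$consistent & cons_b$consistent
}

#' Bootstrapped bivariate Pearson correlation
#'
#' @param x,y paired numeric samples (length >= 3, non-constant).
#' @param B bootstrap resamples (default 1000, >= 100).
#' @param seed integer seed.
#' @param conf confidence level of the percentile interval (default 0.95).
#' @return list with `r`, `ci` (length 2), and `B`.
#' @export
bootstrap_pearson <- function(x, y, B = 1000L, seed = 1L, conf = 0.95) {
  n <- length(x)
  if (length(y) != n || n < 3L)
    rt_error("x and y must be paired with length >= 3", "radtex_invalid_input")
  if (B < 100L) rt_error("B must be >= 100", "radtex_invalid_config")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    rt_error("zero variance sample", "radtex_invalid_input")
  r <- stats::cor(x, y)
  rs <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      i <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) return(NA_real_)
      stats::cor(x[i], y[i])
    }, numeric(1))
  })
  ci <- stats::quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        na.rm = TRUE, names = FALSE)
  list(r = r, ci = ci, B = B)
}
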