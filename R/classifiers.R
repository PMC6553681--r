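# The two classifiers of the evaluation machinery: a linear soft-margin SVM
# (dual coordinate descent on the L1-hinge dual, bias via an augmented
# constant feature) and a gini random forest (compiled, see src/rf.cpp).
# Both expose continuous test scores -- signed margin distance for the SVM,
# fraction of positive tree votes for the forest -- as required for ROC
# analysis, plus the native decision threshold (0 and 0.5 respectively).

#' Fit a linear support vector machine
#'
#' Dual coordinate descent on the L1-loss (hinge) SVM dual with cost `C`,
#' deterministic given `seed`. The bias is absorbed as an augmented constant
#' feature (standard for coordinate-descent linear SVMs).
#'
#' @param X numeric matrix (samples x features), ideally standardized.
#' @param y integer 0/1 labels.
#' @param C soft-margin cost.
#' @param seed integer seed for the coordinate permutation.
#' @param max_pass,tol convergence controls.
#' @return object of class `svm_linear` with weights `w`, bias `b`, and
#'   decision threshold 0.
#' @export
svm_linear <- function(X, y, C = 1, seed = 1L, max_pass = 200L, tol = 1e-4) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    rt_error("both classes required to fit SVM", "radtex_degenerate_fold")
  p <- ncol(X)
  Xa <- cbind(X, 1)
  ys <- ifelse(y == 1L, 1, -1)
  w <- .svm_dcd(Xa, ys, C, as.integer(seed), as.integer(max_pass), tol)
  structure(list(w = w[seq_len(p)], b = w[p + 1L], C = C, threshold = 0),
            class = "svm_linear")
}

#' @rdname svm_linear
#' @param object fitted `svm_linear`.
#' @param newdata numeric matrix with the training feature columns.
#' @param ... unused.
#' @return numeric signed distances to the separating hyperplane (up to the
#'   weight norm), positive = class 1.
#' @export
predict.svm_linear <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$w + object$b)
}

#' Fit a random forest and score test samples
#'
#' Classification forest of `ntree` gini CART trees on bootstrap resamples,
#' `mtry` candidate features per node, grown to purity. Returns the fraction
#' of trees voting for class 1 per test sample (decision threshold 0.5).
#' Deterministic given `seed`.
#'
#' @param X,y training matrix and 0/1 labels.
#' @param Xtest matrix to score.
#' @param mtry candidate features per split.
#' @param ntree number of trees (default 250).
#' @param min_node minimum node size before forcing a leaf (default 1).
#' @param seed integer seed.
#' @return numeric vector of positive-vote fractions for `Xtest` rows.
#' @export
rf_score <- function(X, y, Xtest, mtry = 2L, ntree = 250L, min_node = 1L,
                     seed = 1L) {
  X <- as.matrix(X); Xtest <- as.matrix(Xtest)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    rt_error("both classes required to fit forest", "radtex_degenerate_fold")
  .rf_fit_predict(X, y, Xtest, as.integer(min(mtry, ncol(X))),
                  as.integer(ntree), as.integer(min_node), as.integer(seed))
}
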