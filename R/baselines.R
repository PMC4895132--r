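# Benchmark classifiers: SVM, KNN and LDA under a common
# fit/predict/score contract. These are comparators, not the package's
# contribution: the SVM delegates to e1071; KNN is a small deterministic
# in-package implementation (library KNN breaks distance ties at random,
# which would violate the pure-function contract); LDA is the closed-form
# pooled-covariance discriminant.
#
# The baselines consume features on their native scale: LDA is affine
# invariant, and for the distance-based KNN/SVM the per-dimension spread
# is information (per-dimension range normalization would equalize
# informative and noise axes). Callers with wildly heterogeneous units
# should standardize beforehand.

#' Fit a benchmark classifier
#'
#' \describe{
#'   \item{`svm`}{soft-margin SVM via [e1071::svm()]; default RBF kernel
#'     with `C = 1` and `gamma = 1/(d * var(X))`.}
#'   \item{`knn`}{k-nearest neighbours with the Euclidean metric; stores
#'     the training data. Distance ties are broken by training-row order,
#'     so predictions are deterministic.}
#'   \item{`lda`}{Fisher linear discriminant in closed form with pooled
#'     covariance plus a ridge `epsilon * I` (default
#'     `1e-6 * trace(S)/d`) for invertibility.}
#' }
#'
#' @param kind `"svm"`, `"knn"` or `"lda"`.
#' @param X numeric feature matrix (cases in rows).
#' @param y binary labels; both classes must be present.
#' @param hyperparams kind-specific list: `k` for knn; `kernel`, `C`,
#'   `gamma` for svm; `epsilon` for lda.
#' @return an object of class `baseline_model`.
#' @export
fit_baseline <- function(kind = c("svm", "knn", "lda"), X, y,
                         hyperparams = list()) {
  kind <- match.arg(kind)
  X <- as_row_matrix(X, ncol(X))
  y <- check_labels(y)
  if (length(y) != nrow(X)) stop_input("X and y sizes differ")
  if (length(unique(y)) < 2) stop_input("y must contain both classes")
  if (any(!is.finite(X))) stop_input("X must be finite")
  fit <- switch(kind,
    svm = {
      hp <- utils::modifyList(
        list(kernel = "radial", C = 1,
             gamma = 1 / (ncol(X) * max(var(as.vector(X)), 1e-12))),
        hyperparams)
      m <- e1071::svm(x = X, y = factor(y, levels = c(0, 1)),
                      kernel = hp$kernel, cost = hp$C, gamma = hp$gamma,
                      scale = FALSE)
      list(model = m, hyperparams = hp)
    },
    knn = {
      hp <- utils::modifyList(list(k = 8), hyperparams)
      if (hp$k < 1 || hp$k > nrow(X))
        stop_input("knn k must be in [1, n]")
      list(X = X, y = y, hyperparams = hp)
    },
    lda = {
      hp <- utils::modifyList(list(epsilon = NULL), hyperparams)
      d <- ncol(X)
      mu0 <- colMeans(X[y == 0, , drop = FALSE])
      mu1 <- colMeans(X[y == 1, , drop = FALSE])
      n0 <- sum(y == 0); n1 <- sum(y == 1)
      c0 <- sweep(X[y == 0, , drop = FALSE], 2, mu0)
      c1 <- sweep(X[y == 1, , drop = FALSE], 2, mu1)
      S <- (crossprod(c0) + crossprod(c1)) / (n0 + n1 - 2)
      eps <- if (is.null(hp$epsilon)) 1e-6 * sum(diag(S)) / d else
        hp$epsilon
      Sr <- S + diag(eps, d)
      w <- tryCatch(solve(Sr, mu1 - mu0), error = function(e)
        stop("singular pooled covariance; increase the ridge epsilon"))
      b <- -sum(w * (mu0 + mu1)) / 2 + log(n1 / n0)
      list(w = w, b = b, hyperparams = c(hp, list(epsilon_used = eps)))
    })
  structure(list(kind = kind, fit = fit, n_features = ncol(X),
                 feature_names = colnames(X)),
            class = "baseline_model")
}

# Deterministic Euclidean KNN malignant-neighbour fractions.
knn_scores <- function(train_x, train_y, k, X) {
  d2 <- outer(rowSums(X^2), rowSums(train_x^2), "+") -
    2 * X %*% t(train_x)
  apply(d2, 1, function(row) {
    nn <- order(row)[seq_len(k)]   # order() breaks ties by index
    mean(train_y[nn])
  })
}

#' Continuous malignancy score of a benchmark classifier
#'
#' Higher scores mean more malignant: the signed SVM decision value, the
#' fraction of malignant neighbours for KNN (values in `{0, 1/k, ..., 1}`),
#' or the linear discriminant value for LDA.
#'
#' @param model a [fit_baseline()] result.
#' @param X feature matrix.
#' @return numeric score per row.
#' @export
predict_score <- function(model, X) {
  stopifnot(inherits(model, "baseline_model"))
  X <- as_row_matrix(X, model$n_features)
  switch(model$kind,
    svm = {
      dv <- attr(predict(model$fit$model, X, decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value toward the first factor level
      if (grepl("^0/1", colnames(dv)[1])) -as.numeric(dv) else
        as.numeric(dv)
    },
    knn = knn_scores(model$fit$X, model$fit$y, model$fit$hyperparams$k, X),
    lda = as.numeric(X %*% model$fit$w + model$fit$b))
}

#' Hard class predictions of a benchmark classifier
#'
#' Thresholds the continuous score at 0 (SVM and LDA discriminants) or at
#' a 0.5 neighbour fraction (KNN).
#'
#' @inheritParams predict_score
#' @return integer 0/1 predictions.
#' @export
predict_class <- function(model, X) {
  s <- predict_score(model, X)
  thr <- if (model$kind == "knn") 0.5 else 0
  as.integer(s > thr)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("baseline_model: %s (%d features)\n", x$kind, x$n_features))
  invisible(x)
}
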