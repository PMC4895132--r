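# Evaluation protocol: confusion counts, accuracy/sensitivity/specificity,
# ROC/AUC, stratified 10-fold cross-validation and the three-scenario
# classifier comparison report.

#' Confusion counts
#'
#' @param y_true,y_pred binary vectors of equal length.
#' @return object of class `confusion_counts`: list with `TP`, `FN`, `TN`,
#'   `FP` (with 1 = malignant as the positive class).
#' @export
confusion <- function(y_true, y_pred) {
  y_true <- check_labels(y_true, "y_true")
  y_pred <- check_labels(y_pred, "y_pred")
  if (length(y_true) != length(y_pred))
    stop_input("y_true and y_pred lengths differ")
  structure(list(TP = sum(y_true == 1 & y_pred == 1),
                 FN = sum(y_true == 1 & y_pred == 0),
                 TN = sum(y_true == 0 & y_pred == 0),
                 FP = sum(y_true == 0 & y_pred == 1)),
            class = "confusion_counts")
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `acc = (TP+TN)/n`, `sens = TP/(TP+FN)`, `spec = TN/(TN+FP)`.
#'
#' @param counts a [confusion()] result (or a list with TP/FN/TN/FP).
#' @return named numeric vector `c(accuracy, sensitivity, specificity)`.
#' @export
classification_metrics <- function(counts) {
  with(counts, {
    n <- TP + FN + TN + FP
    if (n == 0) stop_input("accuracy undefined: no observations")
    if (TP + FN == 0)
      stop_input("sensitivity undefined: no positive cases")
    if (TN + FP == 0)
      stop_input("specificity undefined: no negative cases")
    c(accuracy = (TP + TN) / n, sensitivity = TP / (TP + FN),
      specificity = TN / (TN + FP))
  })
}

#' ROC curve and AUC
#'
#' Sweeps all distinct score thresholds (equal scores collapse into one
#' step) and integrates the curve by the trapezoid rule, which equals the
#' Mann-Whitney pair-counting statistic with ties counted one half.
#'
#' @param scores numeric malignancy scores (higher = more malignant).
#' @param y_true binary labels; both classes must be present.
#' @return list with `points` (data frame `fpr`, `tpr`, `threshold`,
#'   starting at (0,0) and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  y_true <- check_labels(y_true, "y_true")
  if (length(scores) != length(y_true))
    stop_input("scores and y_true lengths differ")
  if (any(!is.finite(scores))) stop_input("scores must be finite")
  npos <- sum(y_true == 1); nneg <- sum(y_true == 0)
  if (npos == 0 || nneg == 0)
    stop_input("both classes must be present for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- y_true[ord]
  runs <- rle(s)
  last <- cumsum(runs$lengths)  # last occurrence of each distinct score
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  pts <- data.frame(fpr = c(0, fp / nneg), tpr = c(0, tp / npos),
                    threshold = c(Inf, runs$values))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                pts$tpr[-1]) / 2)
  list(points = pts, auc = auc)
}

# Stratified fold assignment: within each class, shuffled indices are
# dealt round-robin to folds.
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

# Unified fit/predict over the four classifier kinds. spec: list(kind=,
# and for sae: hidden, cfg; for baselines: hyperparams).
fit_classifier <- function(spec, X, y, seed = 1) {
  if (spec$kind == "sae") {
    cfg <- if (!is.null(spec$cfg)) spec$cfg else train_config()
    cfg$seed <- if (!is.null(spec$cfg$seed)) spec$cfg$seed else seed
    sae_train(X, y, hidden = spec$hidden %||% c(200, 200), cfg = cfg)
  } else {
    fit_baseline(spec$kind, X, y, spec$hyperparams %||% list())
  }
}

score_classifier <- function(model, X) {
  if (inherits(model, "sae_classifier")) predict(model, X, type = "score")
  else predict_score(model, X)
}

class_classifier <- function(model, X) {
  if (inherits(model, "sae_classifier")) predict(model, X, type = "class")
  else predict_class(model, X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified k-fold cross-validated accuracy
#'
#' Folds are stratified by class from a seeded shuffle; each fold's model
#' is fitted on the remaining folds only (every classifier fits its
#' scaler on its own training data, so no test-fold statistics leak).
#'
#' @param X feature matrix.
#' @param y binary labels.
#' @param spec classifier specification: `list(kind = "sae", hidden =,
#'   cfg =)` or `list(kind = "svm"|"knn"|"lda", hyperparams =)`.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle (and SAE training).
#' @return list with `mean`, `sd` and `fold_accuracy`.
#' @export
kfold_cv <- function(X, y, spec, k = 10, seed = 1) {
  X <- as_row_matrix(X, ncol(X))
  y <- check_labels(y)
  if (nrow(X) < k) stop_input("need at least k cases")
  if (min(table(y)) < k)
    stop_input("too few cases in a class for ", k, " stratified folds")
  fold <- stratified_folds(y, k, seed)
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    model <- fit_classifier(spec, X[tr, , drop = FALSE], y[tr],
                            seed = seed + f)
    pred <- class_classifier(model, X[!tr, , drop = FALSE])
    mean(pred == y[!tr])
  }, numeric(1))
  list(mean = mean(acc), sd = sd(acc), fold_accuracy = acc)
}

#' Composition of the emulated two-group study cohort
#'
#' The canonical training/testing composition mirrored by the synthetic
#' cohort: 1000 training cases (323 malignant) and 204 test cases (107
#' malignant), with 623/221/156 training cases showing microcalcifications
#' only / masses only / both. Percentages are recomputed from the counts.
#'
#' @return data frame with columns `group`, `stratum`, `count`, `total`
#'   and `percent` (= 100 * count / total, rounded to 1 decimal).
#' @export
study_composition <- function() {
  df <- data.frame(
    group = c("training", "training", "testing", "testing",
              "training", "training", "training"),
    stratum = c("malignant", "benign", "malignant", "benign",
                "calcifications_only", "masses_only",
                "calcifications_and_masses"),
    count = c(323, 677, 107, 97, 623, 221, 156),
    total = c(1000, 1000, 204, 204, 1000, 1000, 1000))
  df$percent <- round(100 * df$count / df$total, 1)
  df
}

#' Simulate the paired train/test cohort tables
#'
#' Draws a training table and a test table with the canonical cohort
#' sizes and class fractions of [study_composition()] (1000 cases at 32.3%
#' malignant for training, 204 at 52.5% for testing) from the same
#' feature-space structure.
#'
#' @param dims 15, 26 or 41.
#' @param structure `"linear"` or `"xor"`.
#' @param effect class separation (see [simulate_feature_table()]).
#' @param seed integer seed.
#' @param n_train,n_test cohort sizes.
#' @return `list(train = list(x, y), test = list(x, y))`.
#' @export
simulate_study_tables <- function(dims, structure = "xor", effect = 3,
                                  seed = 1, n_train = 1000, n_test = 204) {
  train <- simulate_feature_table(n_train, dims, structure, effect,
                                  seed = seed, malignant_fraction = 0.323)
  test <- simulate_feature_table(n_test, dims, structure, effect,
                                 seed = seed + 1,
                                 malignant_fraction = 0.525)
  list(train = train, test = test)
}

scenario_defaults <- function(scenario) {
  switch(scenario,
         calc = list(dims = 15, hidden = c(200, 200), knn_k = 8),
         mass = list(dims = 26, hidden = c(200, 200), knn_k = 8),
         combined = list(dims = 41, hidden = c(400, 400), knn_k = 6))
}

#' Run a full scenario comparison
#'
#' Fits the stacked-autoencoder classifier and the SVM/KNN/LDA benchmarks
#' on the training table, then reports, per classifier, the test-set
#' accuracy, sensitivity, specificity, ROC points and AUC, plus the
#' training-set stratified 10-fold cross-validated accuracy (mean and SD).
#' Scenario defaults: hidden layers `[200, 200]` (calc, mass) or
#' `[400, 400]` (combined); KNN k = 8 (calc, mass) or 6 (combined).
#'
#' @param train,test `list(x =, y =)` tables sharing the scenario's
#'   feature schema (15/26/41 columns).
#' @param scenario `"calc"`, `"mass"` or `"combined"`.
#' @param configs optional overrides: `sae_hidden`, `sae_cfg`, `knn_k`,
#'   `svm`, `lda` (hyperparameter lists), `cv_folds`.
#' @param seed integer seed for CV folds and SAE training.
#' @return an object of class `eval_report`.
#' @export
run_scenario <- function(train, test,
                         scenario = c("combined", "calc", "mass"),
                         configs = list(), seed = 1) {
  scenario <- match.arg(scenario)
  defs <- scenario_defaults(scenario)
  for (tb in list(train, test)) {
    if (is.null(tb$x) || is.null(tb$y))
      stop_input("tables must be lists with x and y")
  }
  if (ncol(train$x) != defs$dims || ncol(test$x) != defs$dims)
    stop_input("tables must have ", defs$dims, " feature columns for the ",
               scenario, " scenario")
  if (!identical(colnames(train$x), colnames(test$x)))
    stop_input("train and test feature schemas differ")
  sae_cfg <- configs$sae_cfg %||% train_config(seed = seed)
  specs <- list(
    SVM = list(kind = "svm", hyperparams = configs$svm %||% list()),
    KNN = list(kind = "knn",
               hyperparams = list(k = configs$knn_k %||% defs$knn_k)),
    LDA = list(kind = "lda", hyperparams = configs$lda %||% list()),
    SAE = list(kind = "sae", hidden = configs$sae_hidden %||% defs$hidden,
               cfg = sae_cfg))
  k <- configs$cv_folds %||% 10
  res <- lapply(specs, function(sp) {
    model <- fit_classifier(sp, train$x, train$y, seed = seed)
    scores <- score_classifier(model, test$x)
    pred <- class_classifier(model, test$x)
    cm <- confusion(test$y, pred)
    met <- classification_metrics(cm)
    roc <- roc_auc(scores, test$y)
    cv <- kfold_cv(train$x, train$y, sp, k = k, seed = seed)
    list(confusion = cm, accuracy = met[["accuracy"]],
         sensitivity = met[["sensitivity"]],
         specificity = met[["specificity"]], auc = roc$auc,
         roc_points = roc$points, cv_mean = cv$mean, cv_sd = cv$sd)
  })
  structure(list(scenario = scenario, classifiers = res, seed = seed,
                 n_train = length(train$y), n_test = length(test$y)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Scenario: %s  (train n=%d, test n=%d)\n", x$scenario,
              x$n_train, x$n_test))
  cat(sprintf("%-5s %9s %12s %12s %6s %16s\n", "", "accuracy",
              "sensitivity", "specificity", "AUC", "CV mean±sd"))
  for (nm in names(x$classifiers)) {
    r <- x$classifiers[[nm]]
    cat(sprintf("%-5s %8.1f%% %12.3f %12.3f %6.3f %9.3f ± %.3f\n", nm,
                100 * r$accuracy, r$sensitivity, r$specificity, r$auc,
                r$cv_mean, r$cv_sd))
  }
  invisible(x)
}

#' Write an evaluation report to JSON and Markdown
#'
#' @param report an [run_scenario()] result.
#' @param json_path,md_path output paths (either may be `NULL`).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, md_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    obj <- list(scenario = report$scenario, seed = report$seed,
                n_train = report$n_train, n_test = report$n_test,
                classifiers = lapply(report$classifiers, function(r) {
                  list(confusion = unclass(r$confusion),
                       accuracy = r$accuracy, sensitivity = r$sensitivity,
                       specificity = r$specificity, auc = r$auc,
                       cv_mean = r$cv_mean, cv_sd = r$cv_sd)
                }))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(md_path)) {
    lines <- c(sprintf("# Scenario: %s", report$scenario), "",
               sprintf("Train n = %d, test n = %d, seed = %d",
                       report$n_train, report$n_test, report$seed), "",
               "| model | accuracy | sensitivity | specificity | AUC | CV mean ± sd |",
               "|-------|----------|-------------|-------------|-----|--------------|")
    for (nm in names(report$classifiers)) {
      r <- report$classifiers[[nm]]
      lines <- c(lines, sprintf(
        "| %s | %.1f%% | %.3f | %.3f | %.3f | %.3f ± %.3f |", nm,
        100 * r$accuracy, r$sensitivity, r$specificity, r$auc,
        r$cv_mean, r$cv_sd))
    }
    writeLines(lines, md_path)
  }
  invisible(report)
}
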