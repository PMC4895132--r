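# Metrics, ROC/AUC, cross-validation and the scenario report.

test_that("confusion counts partition the sample", {
  y <- c(rep(1L, 10), rep(0L, 10))
  cm <- confusion(y, y)
  expect_equal(cm$TP, 10); expect_equal(cm$TN, 10)
  expect_equal(cm$FP + cm$FN, 0)
  allpos <- confusion(y, rep(1L, 20))
  expect_equal(allpos$TP, 10); expect_equal(allpos$FP, 10)
  set.seed(3)
  yp <- sample(0:1, 20, replace = TRUE)
  cm2 <- confusion(y, yp)
  expect_equal(cm2$TP + cm2$FN + cm2$TN + cm2$FP, 20)
  expect_error(confusion(y, yp[-1]), class = "mammocad_input_error")
})

test_that("metric formulas reproduce hand-computed values", {
  m <- classification_metrics(list(TP = 9, FN = 1, TN = 8, FP = 2))
  expect_equal(m[["accuracy"]], 0.85)
  expect_equal(m[["sensitivity"]], 0.90)
  expect_equal(m[["specificity"]], 0.80)
  perfect <- classification_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_equal(as.numeric(perfect), c(1, 1, 1))
  allpos <- classification_metrics(list(TP = 10, FN = 0, TN = 0, FP = 10))
  expect_equal(as.numeric(allpos), c(0.5, 1, 0))
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 5, FP = 5)),
               "sensitivity", class = "mammocad_input_error")
})

test_that("ROC/AUC matches the Mann-Whitney oracle including ties", {
  y <- c(rep(0L, 5), rep(1L, 5))
  expect_equal(roc_auc(c(1:5, 6:10), y)$auc, 1)
  set.seed(5)
  for (i in 1:30) {
    n <- sample(20:200, 1)
    yy <- c(rep(1L, n %/% 3 + 1), rep(0L, n - n %/% 3 - 1))
    s <- sample(round(rnorm(n), 1))          # rounded scores force ties
    r <- roc_auc(s, yy)
    expect_equal(r$auc, auc_pair_counting(s, yy), tolerance = 1e-12)
    expect_equal(1 - r$auc, roc_auc(-s, yy)$auc, tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_equal(unlist(r$points[1, 1:2], use.names = FALSE), c(0, 0))
    expect_equal(unlist(r$points[nrow(r$points), 1:2],
                        use.names = FALSE), c(1, 1))
  }
  expect_error(roc_auc(1:5, rep(1L, 5)), class = "mammocad_input_error")
})

test_that("stratified folds partition the data and preserve class balance", {
  tab <- simulate_feature_table(200, 15, "linear", 1, seed = 2,
                                malignant_fraction = 0.4)
  fold <- mammocad:::stratified_folds(tab$y, 10, seed = 4)
  expect_setequal(fold, 1:10)
  expect_true(all(table(fold) == 20))
  for (f in 1:10) expect_equal(sum(tab$y[fold == f]), 8)
  expect_identical(fold, mammocad:::stratified_folds(tab$y, 10, seed = 4))
})

test_that("cross-validated accuracy of a majority-class learner tracks the majority rate", {
  tab <- simulate_feature_table(200, 15, "linear", 0, seed = 6,
                                malignant_fraction = 0.4)
  cv <- kfold_cv(tab$x, tab$y, list(kind = "knn",
                                    hyperparams = list(k = 180)),
                 k = 10, seed = 3)
  expect_equal(cv$mean, 0.6, tolerance = 0.02)
})

test_that("null-effect tables keep every classifier near chance", {
  tab <- simulate_feature_table(400, 15, "linear", 0, seed = 14)
  for (spec in list(list(kind = "lda"), list(kind = "knn",
                                             hyperparams = list(k = 8)))) {
    cv <- kfold_cv(tab$x, tab$y, spec, k = 10, seed = 5)
    expect_gte(cv$mean, 0.38)
    expect_lte(cv$mean, 0.62)
  }
})

test_that("scenario reports carry four classifiers with consistent metrics", {
  tabs <- simulate_study_tables(15, "linear", 3, seed = 3, n_train = 160,
                                n_test = 60)
  cfg <- train_config(epochs_pretrain = 10, epochs_finetune = 40, seed = 1)
  rep <- run_scenario(tabs$train, tabs$test, "calc",
                      configs = list(sae_hidden = c(12, 12), sae_cfg = cfg,
                                     cv_folds = 4), seed = 2)
  expect_named(rep$classifiers, c("SVM", "KNN", "LDA", "SAE"))
  for (r in rep$classifiers) {
    cm <- r$confusion
    n <- cm$TP + cm$FN + cm$TN + cm$FP
    expect_equal(n, 60)
    expect_equal(r$accuracy * n, cm$TP + cm$TN)   # conservation
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_true(r$cv_sd >= 0)
  }
  rep2 <- run_scenario(tabs$train, tabs$test, "calc",
                       configs = list(sae_hidden = c(12, 12), sae_cfg = cfg,
                                      cv_folds = 4), seed = 2)
  rep$classifiers$SAE$roc_points <- rep2$classifiers$SAE$roc_points
  expect_equal(rep, rep2)
  # schema mismatch
  expect_error(run_scenario(tabs$train, tabs$test, "mass"),
               class = "mammocad_input_error")
  # report files
  jp <- file.path(tempdir(), "rep.json"); mp <- file.path(tempdir(), "rep.md")
  write_report(rep, jp, mp)
  expect_true(file.exists(jp) && file.exists(mp))
  got <- jsonlite::read_json(jp)
  expect_equal(got$classifiers$SAE$accuracy,
               rep$classifiers$SAE$accuracy, tolerance = 1e-9)
})
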