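# small separable feature set used across adapter tests
toy_features <- function(n_per_class = 12, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * 4, 0), ncol = 4),
             matrix(rnorm(n_per_class * 4, 3), ncol = 4))
  list(x = x, y = rep(c("a", "b"), each = n_per_class))
}

test_that("stratified split preserves proportions exactly when possible", {
  labels <- rep(c("A", "B"), c(60, 40))
  idx <- stratified_split_idx(labels, split_plan(0.2, seed = 1))
  expect_length(idx$test, 20)
  expect_equal(sum(labels[idx$test] == "A"), 12)
  expect_equal(sum(labels[idx$test] == "B"), 8)
  expect_setequal(c(idx$train, idx$test), seq_along(labels))
  expect_length(intersect(idx$train, idx$test), 0)
  idx2 <- stratified_split_idx(labels, split_plan(0.2, seed = 1))
  expect_identical(idx, idx2)
  expect_error(stratified_split_idx(c("A", "B", "B"), split_plan()),
               "at least 2")
})

test_that("stratified folds balance every class within one sample", {
  labels <- rep(c("a", "b", "c"), c(11, 10, 15))
  fold <- stratified_folds(labels, k = 5, seed = 2)
  for (cl in unique(labels)) {
    sizes <- table(fold[labels == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_identical(fold, stratified_folds(labels, k = 5, seed = 2))
})

test_that("precision, recall and accuracy follow the confusion arithmetic", {
  expect_equal(precision(96, 4), 0.96)
  expect_equal(precision(5, 0), 1)
  expect_warning(p0 <- precision(0, 0), "undefined")
  expect_equal(p0, 0)
  expect_equal(recall(97, 3), 0.97)
  expect_equal(recall(1, 0), 1)
  expect_warning(r0 <- recall(0, 0), "undefined")
  expect_equal(r0, 0)
  expect_equal(accuracy(59, 60), 100 * 59 / 60)
  expect_equal(accuracy(0, 10), 0)
  expect_equal(accuracy(10, 10), 100)
  expect_error(precision(-1, 0), "non-negative")
  expect_error(accuracy(5, 0), "at least 1")
})

test_that("ROC staircase runs (0,0) to (1,1), monotone, correct areas", {
  r <- roc_points(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1); expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(attr(r, "auc"), 1)
  expect_true(any(r$fpr == 0 & r$tpr == 1))   # perfect separation
  tied <- roc_points(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(nrow(tied), 2)
  expect_equal(attr(tied, "auc"), 0.5)
  expect_error(roc_points(c(0.1, 0.2), c(1, 1)), "positive and one negative")
})

test_that("ROC area agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:5) {
    lab <- sample(c(0, 1), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(lab)) < 2) next
    sc <- rnorm(40) + lab
    mine <- attr(roc_points(sc, lab), "auc")
    ref <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("every classifier adapter fits, predicts and scores sanely", {
  d <- toy_features()
  for (name in c("rf", "gb", "knn", "ann", "svc")) {
    model <- fit_classifier(name, d$x, d$y, seed = 7)
    pred <- predict_classifier(model, d$x)
    expect_length(pred$labels, nrow(d$x))
    expect_equal(dim(pred$prob), c(nrow(d$x), 2))
    expect_equal(unname(rowSums(pred$prob)), rep(1, nrow(d$x)),
                 tolerance = 1e-6)
    expect_gt(mean(pred$labels == d$y), 0.9)   # separable training data
  }
  expect_error(fit_classifier("lda", d$x, d$y), "arg")
})

test_that("manhattan and euclidean k-NN can disagree, both deterministic", {
  x <- rbind(c(0, 0), c(1.2, 0), c(0, 1.2), c(3, 3))
  y <- c("a", "a", "a", "b")
  m1 <- fit_classifier("knn", x, y, params = list(k = 1, metric = "euclidean"))
  m2 <- fit_classifier("knn", x, y, params = list(k = 1, metric = "manhattan"))
  q <- matrix(c(2, 2), 1)
  p1 <- predict_classifier(m1, q)
  p2 <- predict_classifier(m2, q)
  # euclidean: (3,3) at sqrt(2) beats (1.2,0) at ~2.2; manhattan ties resolve
  # to the listed order deterministically
  expect_identical(p1$labels, "b")
  expect_identical(p2$labels,
                   predict_classifier(m2, q)$labels)
})

test_that("predicting with mismatched feature length is rejected", {
  d <- toy_features()
  model <- fit_classifier("knn", d$x, d$y)
  expect_error(predict_classifier(model, d$x[, 1:3]), "mismatch")
})

test_that("evaluation report matches a hand-built confusion table", {
  # stub model: predicts via a fixed lookup, 3 classes
  truth <- c("a", "a", "a", "b", "b", "b", "c", "c", "c", "c")
  predd <- c("a", "a", "b", "b", "b", "c", "c", "c", "c", "a")
  stub <- structure(list(name = "knn",
                         fit = list(train_x = diag(3)[c(1, 2, 3), ],
                                    train_y = factor(c("a", "b", "c")),
                                    k = 1, metric = "euclidean"),
                         classes = c("a", "b", "c"), n_features = 3),
                    class = "meshtex_model")
  x <- diag(3)[match(predd, c("a", "b", "c")), ]
  rep <- evaluate_classifier(stub, x, truth)
  expect_equal(rep$accuracy, 70)   # 7 of 10 on the diagonal
  pc <- rep$per_class
  expect_equal(pc$precision[pc$class == "a"], 2 / 3)   # TP 2, FP 1
  expect_equal(pc$recall[pc$class == "a"], 2 / 3)      # FN 1
  expect_equal(pc$precision[pc$class == "c"], 3 / 4)
  expect_equal(pc$recall[pc$class == "c"], 3 / 4)
  expect_equal(sum(diag(rep$confusion)), 7)
  expect_true(all(pc$precision >= 0 & pc$precision <= 1))
})

test_that("perfect and constant predictors hit the metric extremes", {
  d <- toy_features()
  model <- fit_classifier("knn", d$x, d$y, params = list(k = 1))
  rep <- evaluate_classifier(model, d$x, d$y)   # 1-NN on train: perfect
  expect_equal(rep$accuracy, 100)
  expect_true(all(rep$per_class$precision == 1))
  expect_true(all(rep$per_class$recall == 1))
  # constant predictor: non-predicted class has recall 0
  truth2 <- c("a", "a", "b", "b")
  x2 <- matrix(0, 4, 3)
  stub <- structure(list(name = "knn",
                         fit = list(train_x = matrix(0, 2, 3),
                                    train_y = factor(c("a", "a"),
                                                     levels = c("a", "b")),
                                    k = 1, metric = "euclidean"),
                         classes = c("a", "b"), n_features = 3),
                    class = "meshtex_model")
  rep2 <- suppressWarnings(evaluate_classifier(stub, x2, truth2))
  expect_equal(rep2$per_class$recall[rep2$per_class$class == "b"], 0)
})

test_that("cross-validation keeps augmented variants with their parent fold", {
  set.seed(3)
  n <- 20
  y <- rep(c("a", "b"), each = n / 2)
  origin <- c(seq_len(n), seq_len(n))          # one variant per original
  yy <- c(y, y)
  fold_orig <- stratified_folds(y, k = 5, seed = 11)
  fold <- fold_orig[origin]
  for (f in 1:5) {
    tr <- which(fold != f)
    va_orig <- intersect(which(fold == f), seq_len(n))
    # no training sample may share provenance with a validation original
    expect_length(intersect(origin[tr], origin[va_orig]), 0)
  }
})

test_that("train_with_gwo returns a refit model and beats its own defaults", {
  d <- toy_features(n_per_class = 15, seed = 5)
  res <- train_with_gwo(d$x, d$y, spec = classifier_spec("knn"),
                        plan = split_plan(k_folds = 3, seed = 1),
                        gwo = gwo_config(4, 3, seed = 1))
  expect_s3_class(res$model, "meshtex_model")
  expect_gte(res$opt$best_fitness, res$default_fitness)
  res2 <- train_with_gwo(d$x, d$y, spec = classifier_spec("knn"),
                         plan = split_plan(k_folds = 3, seed = 1),
                         gwo = gwo_config(4, 3, seed = 1))
  expect_identical(res$opt$best_params, res2$opt$best_params)
})
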