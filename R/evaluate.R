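# Evaluation protocol: stratified splitting and k-folds, precision /
# recall / accuracy from confusion counts, and one-vs-rest ROC curves.

#' Train/test split plan
#'
#' @param test_fraction Fraction of each class held out for testing
#'   (default 0.2, the 80:20 split).
#' @param k_folds Folds for cross-validated tuning (default 5).
#' @param seed Integer seed for the shuffles.
#' @return A `split_plan` list.
#' @export
split_plan <- function(test_fraction = 0.2, k_folds = 5L, seed = 0L) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("`test_fraction` must lie in (0, 1)")
  structure(list(test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 seed = as.integer(seed), stratified = TRUE),
            class = "split_plan")
}

# per-class held-out counts by largest-remainder allocation
stratified_test_counts <- function(labels, test_fraction) {
  tab <- table(labels)
  raw <- as.numeric(tab) * test_fraction
  n_test <- floor(raw)
  rem <- round(sum(raw)) - sum(n_test)
  if (rem > 0) {
    give <- order(-(raw - n_test))[seq_len(rem)]
    n_test[give] <- n_test[give] + 1
  }
  stats::setNames(as.integer(n_test), names(tab))
}

#' Stratified train/test split of index vectors
#'
#' @param labels Class labels, one per sample.
#' @param plan A [split_plan()].
#' @return List with integer index vectors `train` and `test`; class
#'   proportions in the test set match the global proportions within
#'   one sample, the two sets are disjoint and cover all samples, and
#'   the partition is deterministic under the plan's seed.
#' @export
stratified_split_idx <- function(labels, plan = split_plan()) {
  tab <- table(labels)
  if (any(tab < 2L)) stop("every class needs at least 2 samples to split")
  counts <- stratified_test_counts(labels, plan$test_fraction)
  with_seed(plan$seed, {
    test <- integer(0)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      test <- c(test, sample(idx)[seq_len(counts[[cl]])])
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' Split a labeled set into train and test subsets
#'
#' @param set A `labeled_set`.
#' @param plan A [split_plan()].
#' @return List of two `labeled_set`s, `train` and `test`.
#' @export
stratified_split <- function(set, plan = split_plan()) {
  stopifnot(inherits(set, "labeled_set"))
  idx <- stratified_split_idx(set$labels, plan)
  subset_ls <- function(i)
    labeled_set(set$images[i], set$labels[i], class_names = set$class_names,
                origin = seq_along(i))
  list(train = subset_ls(idx$train), test = subset_ls(idx$test))
}

#' Stratified k-fold assignment
#'
#' @param labels Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k, one per sample; per-class
#'   fold sizes differ by at most one.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 0L) {
  if (any(table(labels) < k))
    stop("every class needs at least k samples for k folds")
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Precision from confusion counts
#'
#' `TP / (TP + FP)`; 0 (with a warning) when no positive predictions
#' were made.
#'
#' @param t_pos True-positive count.
#' @param f_pos False-positive count.
#' @return A rate in \[0, 1\].
#' @export
precision <- function(t_pos, f_pos) {
  if (t_pos < 0 || f_pos < 0) stop("counts must be non-negative")
  if (t_pos + f_pos == 0) {
    warning("precision undefined (no positive predictions); returning 0")
    return(0)
  }
  t_pos / (t_pos + f_pos)
}

#' Recall (sensitivity) from confusion counts
#'
#' `TP / (TP + FN)`; 0 (with a warning) when the class has no true
#' members.
#'
#' @param t_pos True-positive count.
#' @param f_neg False-negative count.
#' @return A rate in \[0, 1\].
#' @export
recall <- function(t_pos, f_neg) {
  if (t_pos < 0 || f_neg < 0) stop("counts must be non-negative")
  if (t_pos + f_neg == 0) {
    warning("recall undefined (no true positives or false negatives); returning 0")
    return(0)
  }
  t_pos / (t_pos + f_neg)
}

#' Overall accuracy as a percentage
#'
#' `100 * correct / total`.
#'
#' @param n_correct Number of correct predictions.
#' @param n_total Total number of predictions (>= 1).
#' @return Percentage in \[0, 100\].
#' @export
accuracy <- function(n_correct, n_total) {
  if (n_total < 1) stop("`n_total` must be at least 1")
  if (n_correct < 0 || n_correct > n_total)
    stop("`n_correct` must lie in [0, n_total]")
  100 * n_correct / n_total
}

#' ROC curve points
#'
#' Sweeps the decision threshold over every observed score and records
#' the (false-positive rate, true-positive rate) staircase, from (0, 0)
#' at the strictest threshold to (1, 1) at the loosest. Both coordinates
#' are non-decreasing.
#'
#' @param scores Numeric positive-class scores, one per sample.
#' @param labels Binary labels (logical, or values in \{0, 1\}).
#' @return Data frame with columns `fpr` and `tpr` and the area under
#'   the staircase as attribute `auc`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC needs at least one positive and one negative label")
  o <- order(-scores)
  s <- scores[o]; l <- labels[o]
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- c(s[-1] != s[-length(s)], TRUE)  # keep one point per threshold
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

# per-class confusion counts from predicted/true label vectors
confusion_counts <- function(true, pred, classes) {
  lapply(stats::setNames(classes, classes), function(cl) {
    list(t_pos = sum(pred == cl & true == cl),
         f_pos = sum(pred == cl & true != cl),
         f_neg = sum(pred != cl & true == cl),
         t_neg = sum(pred != cl & true != cl))
  })
}

#' Evaluate a fitted classifier on a test set
#'
#' Computes the confusion counts, per-class precision and recall,
#' overall accuracy (percent), and one-vs-rest ROC curves with their
#' AUCs.
#'
#' @param model A `meshtex_model`.
#' @param x Test feature matrix.
#' @param y Test labels.
#' @return An `eval_report` list: `accuracy`, `confusion` (class x class
#'   count matrix, rows = truth), `per_class` (data frame of counts,
#'   precision, recall), `roc` (per-class list of [roc_points()]
#'   frames), `auc` (named vector), `predictions`.
#' @export
evaluate_classifier <- function(model, x, y) {
  if (length(y) == 0L) stop("test set is empty")
  pred <- predict_classifier(model, x)
  classes <- model$classes
  true <- factor(as.character(y), levels = classes)
  phat <- factor(pred$labels, levels = classes)
  conf <- table(truth = true, prediction = phat)
  counts <- confusion_counts(as.character(true), pred$labels, classes)
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    cc <- counts[[cl]]
    data.frame(class = cl, t_pos = cc$t_pos, f_pos = cc$f_pos,
               f_neg = cc$f_neg, t_neg = cc$t_neg,
               precision = suppressWarnings(precision(cc$t_pos, cc$f_pos)),
               recall = suppressWarnings(recall(cc$t_pos, cc$f_neg)))
  }))
  roc <- list(); auc <- numeric(0)
  for (cl in classes) {
    pos <- as.character(true) == cl
    if (any(pos) && !all(pos)) {
      r <- roc_points(pred$prob[, cl], pos)
      roc[[cl]] <- r
      auc[cl] <- attr(r, "auc")
    }
  }
  structure(list(accuracy = accuracy(sum(pred$labels == as.character(true)),
                                     length(y)),
                 confusion = conf, per_class = per_class,
                 roc = roc, auc = auc, predictions = pred),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report: accuracy %.2f%%>\n", x$accuracy))
  print(x$confusion)
  print(x$per_class[, c("class", "precision", "recall")], row.names = FALSE)
  invisible(x)
}
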