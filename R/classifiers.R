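# Classifier adapters. The bespoke science here is the descriptor, the
# optimizer and the protocol; the classifiers themselves are textbook
# models, so each adapter wraps an established implementation behind a
# uniform fit/predict surface:
#   rf  -> ranger        (random forest)
#   gb  -> xgboost       (gradient boosting)
#   knn -> small in-package k-NN (class::knn lacks the manhattan metric
#          the search space tunes over, so the vote is done here)
#   ann -> nnet          (single-hidden-layer feed-forward network)
#   svc -> e1071::svm    (support vector classifier)

#' Classifier specification
#'
#' Names one of the five supported classifiers together with its
#' hyperparameter search space and defaults. The tuned hyperparameters
#' follow the published protocol: trees / depth / node size for the
#' random forest; learning rate / rounds / depth for gradient boosting;
#' neighbor count and distance metric for k-NN; hidden-layer size,
#' weight decay and training epochs for the network adapter;
#' regularization constant and kernel for the SVC.
#'
#' @param name One of `"rf"`, `"gb"`, `"knn"`, `"ann"`, `"svc"`.
#' @return A `classifier_spec` list with `name`, `space`
#'   (a [search_space()]) and `defaults` (named list).
#' @export
classifier_spec <- function(name = c("rf", "gb", "knn", "ann", "svc")) {
  name <- match.arg(name)
  sp <- switch(name,
    rf = list(space = search_space(
                num_trees = dim_integer(50, 300),
                max_depth = dim_integer(2, 20),
                min_node_size = dim_integer(1, 10)),
              defaults = list(num_trees = 100L, max_depth = 10L,
                              min_node_size = 1L)),
    gb = list(space = search_space(
                learning_rate = dim_continuous(0.01, 0.3),
                n_estimators = dim_integer(20, 150),
                max_depth = dim_integer(1, 6)),
              defaults = list(learning_rate = 0.1, n_estimators = 50L,
                              max_depth = 3L)),
    knn = list(space = search_space(
                 k = dim_integer(1, 15),
                 metric = dim_categorical(c("euclidean", "manhattan"))),
               defaults = list(k = 5L, metric = "euclidean")),
    ann = list(space = search_space(
                 size = dim_integer(2, 12),
                 decay = dim_continuous(1e-4, 0.5),
                 maxit = dim_integer(50, 300)),
               defaults = list(size = 5L, decay = 1e-3, maxit = 100L)),
    svc = list(space = search_space(
                 cost = dim_continuous(0.01, 100),
                 kernel = dim_categorical(c("linear", "radial", "polynomial",
                                            "sigmoid"))),
               defaults = list(cost = 1, kernel = "radial")))
  structure(list(name = name, space = sp$space, defaults = sp$defaults),
            class = "classifier_spec")
}

#' Fit a classifier
#'
#' @param spec A [classifier_spec()] (or its name).
#' @param x Numeric feature matrix, one row per sample.
#' @param y Class labels (character or factor).
#' @param params Named list of hyperparameters; missing entries fall
#'   back to the classifier's defaults.
#' @param seed Integer seed for stochastic fitters.
#' @return A `meshtex_model` holding the fitted backend and metadata.
#' @export
fit_classifier <- function(spec, x, y, params = list(), seed = 0L) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  stopifnot(inherits(spec, "classifier_spec"))
  p <- utils::modifyList(spec$defaults, params)
  y <- factor(y)
  classes <- levels(y)
  x <- as.matrix(x)
  colnames(x) <- feature_names(ncol(x), colnames(x))
  fit <- with_seed(seed, switch(spec$name,
    rf = ranger::ranger(x = x, y = y, num.trees = p$num_trees,
                        max.depth = p$max_depth,
                        min.node.size = p$min_node_size,
                        probability = TRUE, num.threads = 1L,
                        seed = seed),
    gb = {
      nc <- length(classes)
      obj <- if (nc > 2L) "multi:softprob" else "binary:logistic"
      pars <- list(eta = p$learning_rate, max_depth = p$max_depth,
                   objective = obj, nthread = 1L)
      if (nc > 2L) pars$num_class <- nc
      xgboost::xgb.train(params = pars,
                         data = xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L),
                         nrounds = p$n_estimators, verbose = 0)
    },
    knn = list(train_x = as.matrix(x), train_y = y, k = p$k,
               metric = p$metric),
    ann = nnet::nnet(x = as.matrix(x), y = stats::model.matrix(~ y - 1),
                     size = p$size, decay = p$decay, maxit = p$maxit,
                     softmax = TRUE, MaxNWts = 200000L, trace = FALSE),
    svc = e1071::svm(x = as.matrix(x), y = y, cost = p$cost,
                     kernel = p$kernel, probability = TRUE)))
  structure(list(name = spec$name, fit = fit, classes = classes,
                 params = p, n_features = ncol(x)),
            class = "meshtex_model")
}

#' Predict class labels and per-class scores
#'
#' @param model A `meshtex_model` from [fit_classifier()].
#' @param x Feature matrix with the same number of columns as used in
#'   training.
#' @return List with `labels` (character) and `prob` (matrix, one
#'   column per class, rows summing to 1).
#' @export
predict_classifier <- function(model, x) {
  stopifnot(inherits(model, "meshtex_model"))
  x <- as.matrix(x)
  colnames(x) <- feature_names(ncol(x), colnames(x))
  if (ncol(x) != model$n_features)
    stop(sprintf("feature length mismatch: model trained on %d, got %d",
                 model$n_features, ncol(x)))
  prob <- switch(model$name,
    rf = stats::predict(model$fit, data = x, num.threads = 1L)$predictions,
    gb = {
      raw <- stats::predict(model$fit, xgboost::xgb.DMatrix(x))
      nc <- length(model$classes)
      if (nc > 2L) matrix(raw, ncol = nc) else cbind(1 - raw, raw)
    },
    knn = knn_prob(model$fit, x),
    ann = {
      raw <- stats::predict(model$fit, x)
      if (ncol(raw) == 1L) cbind(1 - raw[, 1], raw[, 1]) else raw
    },
    svc = {
      pr <- attr(stats::predict(model$fit, x, probability = TRUE),
                 "probabilities")
      pr[, model$classes, drop = FALSE]
    })
  colnames(prob) <- model$classes
  labels <- model$classes[max.col(prob, ties.method = "first")]
  list(labels = labels, prob = prob)
}

# some backends insist on named covariates
feature_names <- function(n, existing) {
  if (is.null(existing)) sprintf("f%04d", seq_len(n)) else existing
}

# k-NN vote probabilities; ties in the vote resolve to the class whose
# voting neighbors are nearest in total (then by class order)
knn_prob <- function(fit, x) {
  tr <- fit$train_x
  metric_pow <- if (fit$metric == "manhattan") 1 else 2
  classes <- levels(fit$train_y)
  k <- min(fit$k, nrow(tr))
  prob <- matrix(0, nrow(x), length(classes),
                 dimnames = list(NULL, classes))
  for (r in seq_len(nrow(x))) {
    d <- if (metric_pow == 1) colSums(abs(t(tr) - x[r, ]))
         else sqrt(colSums((t(tr) - x[r, ])^2))
    nn <- order(d)[seq_len(k)]
    votes <- table(factor(fit$train_y[nn], levels = classes))
    prob[r, ] <- as.numeric(votes) / k
    top <- which(votes == max(votes))
    if (length(top) > 1L) {     # nudge the vote toward the nearest class
      sums <- vapply(names(votes)[top], function(cl)
        sum(d[nn][fit$train_y[nn] == cl]), numeric(1))
      win <- names(votes)[top[which.min(sums)]]
      prob[r, win] <- prob[r, win] + 1e-9
    }
  }
  prob / rowSums(prob)
}
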