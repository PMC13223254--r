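# GWO-tuned training: the fitness of a hyperparameter assignment is its
# mean validation accuracy over stratified folds of the training split.
# Augmented variants always stay on their original's side of each fold
# boundary, and validation is scored on originals only, so no variant
# of a validation image ever reaches the training side (no leakage).

#' Cross-validated accuracy of one hyperparameter assignment
#'
#' Folds are assigned to original images; every augmented variant
#' inherits its parent's fold. For fold f the model trains on all
#' samples (originals and variants) of the other folds and is scored on
#' the originals of fold f.
#'
#' @param x Feature matrix (training split: originals plus variants).
#' @param y Labels parallel to `x`.
#' @param origin Integer vector mapping each row to its original.
#' @param spec A [classifier_spec()].
#' @param params Hyperparameter assignment to score.
#' @param plan A [split_plan()] (uses `k_folds` and `seed`).
#' @return Mean validation accuracy over folds, as a fraction in
#'   \[0, 1\].
#' @export
cv_accuracy <- function(x, y, origin, spec, params, plan = split_plan()) {
  originals <- which(origin == seq_along(origin))
  fold_of_original <- rep(NA_integer_, length(y))
  fold_of_original[originals] <-
    stratified_folds(y[originals], k = plan$k_folds, seed = plan$seed)
  fold <- fold_of_original[origin]          # variants inherit parent fold
  accs <- vapply(seq_len(plan$k_folds), function(f) {
    tr <- which(fold != f)
    va <- intersect(which(fold == f), originals)
    model <- fit_classifier(spec, x[tr, , drop = FALSE], y[tr],
                            params = params, seed = plan$seed + f)
    pred <- predict_classifier(model, x[va, , drop = FALSE])
    mean(pred$labels == y[va])
  }, numeric(1))
  mean(accs)
}

#' Train a classifier with Grey-Wolf-optimized hyperparameters
#'
#' Runs GWO over the classifier's search space, with mean stratified
#' k-fold validation accuracy on the training split as the fitness.
#' The classifier's default hyperparameters are seeded into the initial
#' pack, so the tuned validation accuracy can never fall below the
#' default configuration's. The final model is refit on the full
#' training split with the best assignment.
#'
#' @param x Training feature matrix.
#' @param y Training labels.
#' @param spec A [classifier_spec()] or classifier name.
#' @param plan A [split_plan()] controlling the tuning folds.
#' @param gwo A [gwo_config()].
#' @param origin Optional provenance vector (see [cv_accuracy()]);
#'   defaults to all-original.
#' @return List with `model` (the refit `meshtex_model`), `opt` (the
#'   `opt_result`), and `default_fitness` (the default assignment's
#'   cross-validated accuracy, for with/without-tuning comparisons).
#' @export
train_with_gwo <- function(x, y, spec = classifier_spec("rf"),
                           plan = split_plan(), gwo = gwo_config(),
                           origin = seq_along(y)) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  if (any(table(y[origin == seq_along(origin)]) < plan$k_folds))
    stop("every class needs at least k_folds original training samples")
  fitness <- function(asg) cv_accuracy(x, y, origin, spec, asg, plan)
  default_fitness <- fitness(spec$defaults)
  opt <- gwo_optimize(fitness, spec$space, gwo, init = list(spec$defaults))
  model <- fit_classifier(spec, x, y, params = opt$best_params,
                          seed = plan$seed)
  list(model = model, opt = opt, default_fitness = default_fitness)
}
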