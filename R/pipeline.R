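# End-to-end pipeline: fixtures -> preprocess -> AM-LMTP features ->
# GWO-tuned classifier -> evaluation report. A flat key=value config
# file captures every parameter so a run is reconstructible from the
# emitted config and seed alone.

#' Pipeline run configuration
#'
#' Bundles the stage parameters with a master seed. Defaults reproduce
#' the published operating point: CLAHE clip limit 2.0, gamma 0.4,
#' sharpening strength 1.0, adaptive threshold alpha = 0.2 and
#' beta_offset = 5, scales 3 and 7, random forest with 5-fold tuning on
#' an 80:20 stratified split, two augmented variants per training
#' original.
#'
#' @param classifier Classifier name (see [classifier_spec()]).
#' @param n_per_class Fixture images per class in demo mode.
#' @param image_size Fixture image side length (square).
#' @param clip_limit,tile_grid,gamma,sharpen_strength,clahe_mode
#'   Preprocessing parameters (see [preprocess_config()]).
#' @param alpha,beta_offset Adaptive-threshold parameters.
#' @param scales Integer window sizes for the descriptor.
#' @param test_fraction,k_folds Evaluation protocol parameters.
#' @param variants_per_original Train-only augmentation count.
#' @param n_wolves,n_iters GWO budget.
#' @param seed Master seed; every stage seed derives from it.
#' @return A `run_config` list.
#' @export
run_config <- function(classifier = "rf", n_per_class = 30L, image_size = 32L,
                       clip_limit = 2.0, tile_grid = 8L, gamma = 0.4,
                       sharpen_strength = 1.0, clahe_mode = "clahe",
                       alpha = 0.2, beta_offset = 5, scales = c(3L, 7L),
                       test_fraction = 0.2, k_folds = 5L,
                       variants_per_original = 2L,
                       n_wolves = 6L, n_iters = 8L, seed = 0L) {
  structure(list(classifier = classifier, n_per_class = as.integer(n_per_class),
                 image_size = as.integer(image_size), clip_limit = clip_limit,
                 tile_grid = as.integer(tile_grid), gamma = gamma,
                 sharpen_strength = sharpen_strength, clahe_mode = clahe_mode,
                 alpha = alpha, beta_offset = beta_offset,
                 scales = as.integer(scales),
                 test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 variants_per_original = as.integer(variants_per_original),
                 n_wolves = as.integer(n_wolves), n_iters = as.integer(n_iters),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Write / read a run configuration as flat key=value text
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  vals <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(p[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  }), vapply(kv, `[[`, character(1), 1))
  do.call(run_config, vals)
}

#' Run the full pipeline on a labeled set
#'
#' Splits 80:20 stratified, augments the training split (train-only),
#' preprocesses and extracts AM-LMTP features, tunes the classifier
#' with GWO on stratified training folds, refits on the full training
#' split and evaluates on the untouched test split.
#'
#' @param set A `labeled_set` of original (non-augmented) images.
#' @param cfg A [run_config()].
#' @return A `pipeline_result`: `report` (test-set `eval_report`),
#'   `opt`, `default_fitness`, `tuned_fitness`, `model`, `config`,
#'   and `features` (list with train/test matrices and labels).
#' @export
run_pipeline <- function(set, cfg = run_config()) {
  stopifnot(inherits(set, "labeled_set"))
  pre <- preprocess_config(clip_limit = cfg$clip_limit,
                           tile_grid = rep(cfg$tile_grid, 2L),
                           gamma = cfg$gamma,
                           sharpen_strength = cfg$sharpen_strength,
                           clahe_mode = cfg$clahe_mode)
  tg <- cfg$tile_grid
  if (tg > cfg$image_size)   # small demo images: shrink the tile grid
    pre$tile_grid <- c(4L, 4L)
  params <- threshold_params(alpha = cfg$alpha, beta_offset = cfg$beta_offset)
  scales <- lapply(cfg$scales, mesh_scale)
  plan <- split_plan(test_fraction = cfg$test_fraction, k_folds = cfg$k_folds,
                     seed = cfg$seed)
  split <- stratified_split(set, plan)
  train <- if (cfg$variants_per_original > 0L)
    augment(split$train, augment_policy(cfg$variants_per_original,
                                        seed = cfg$seed))
  else split$train
  ftr <- extract_feature_matrix(train, cfg = pre, params = params,
                                scales = scales)
  fte <- extract_feature_matrix(split$test, cfg = pre, params = params,
                                scales = scales)
  tuned <- train_with_gwo(ftr$features, ftr$labels,
                          spec = classifier_spec(cfg$classifier),
                          plan = plan,
                          gwo = gwo_config(n_wolves = cfg$n_wolves,
                                           n_iters = cfg$n_iters,
                                           seed = cfg$seed),
                          origin = ftr$origin)
  report <- evaluate_classifier(tuned$model, fte$features, fte$labels)
  structure(list(report = report, opt = tuned$opt,
                 default_fitness = tuned$default_fitness,
                 tuned_fitness = tuned$opt$best_fitness,
                 model = tuned$model, config = cfg,
                 features = list(train = ftr, test = fte)),
            class = "pipeline_result")
}

#' Run the self-contained demo pipeline
#'
#' Generates the three-class synthetic texture set (smooth / speckle /
#' grating) and runs [run_pipeline()] on it; the whole run is
#' deterministic in the config seed.
#'
#' @param cfg A [run_config()].
#' @return A `pipeline_result` (see [run_pipeline()]).
#' @export
run_demo <- function(cfg = run_config()) {
  set <- make_labeled_set(cfg$n_per_class,
                          classes = c("smooth", "speckle", "grating"),
                          size = rep(cfg$image_size, 2L), seed = cfg$seed + 1L)
  run_pipeline(set, cfg)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0("<pipeline_result: %s, test accuracy %.2f%%, ",
                     "tuned CV %.4f vs default CV %.4f>\n"),
              x$model$name, x$report$accuracy, x$tuned_fitness,
              x$default_fitness))
  invisible(x)
}

#' Export a pipeline report as JSON
#'
#' @param result A `pipeline_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(result, path) {
  rep <- result$report
  out <- list(
    classifier = result$model$name,
    accuracy_percent = rep$accuracy,
    per_class = rep$per_class,
    auc = as.list(rep$auc),
    roc = lapply(rep$roc, function(r) list(fpr = r$fpr, tpr = r$tpr)),
    best_params = result$opt$best_params,
    tuned_cv_accuracy = result$tuned_fitness,
    default_cv_accuracy = result$default_fitness,
    fitness_history = result$opt$history,
    seed = result$config$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
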