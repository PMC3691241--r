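#' @importFrom randomForest randomForest
#' @importFrom stats predict sd
NULL

#' Confusion matrix for a binary classifier
#'
#' @param tp,tn,fp,fn Non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    abort_validation("confusion matrix counts must be non-negative integers")
  if (sum(counts) == 0)
    abort_validation("confusion matrix is all zero")
  structure(as.list(counts), class = "confusion_matrix")
}

safe_ratio <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); reporting 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' The five evaluation metrics of a confusion matrix
#'
#' Accuracy, sensitivity, specificity and precision as percentages;
#' Matthews correlation coefficient (MCC) in \[-1, 1\]. A zero denominator
#' yields 0 (with a warning for Sn/Sp/Pr; silently for MCC, the usual
#' convention for degenerate matrices).
#'
#' @param cm A [confusion_matrix()].
#' @return A list of class `metrics_report` with elements `acc`, `sn`,
#'   `sp`, `pr` (percentages) and `mcc`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  total <- tp + tn + fp + fn
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  structure(list(
    acc = 100 * (tp + tn) / total,
    sn  = 100 * safe_ratio(tp, tp + fn, "sensitivity"),
    sp  = 100 * safe_ratio(tn, tn + fp, "specificity"),
    pr  = 100 * safe_ratio(tp, tp + fp, "precision"),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Acc %.2f%%  Sn %.2f%%  Sp %.2f%%  Pr %.2f%%  MCC %.2f\n",
              x$acc, x$sn, x$sp, x$pr, x$mcc))
  invisible(x)
}

#' Random-forest configuration
#'
#' @param num_trees Number of trees grown.
#' @param num_features Features tried at each split (`mtry`); `NULL` means
#'   `ceiling(sqrt(d))` at training time.
#' @param seed Integer seed; training and cross-validation are
#'   deterministic given the seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(num_trees = 100L, num_features = NULL, seed = 1L) {
  stopifnot(num_trees >= 1L, is.null(num_features) || num_features >= 1L)
  structure(list(num_trees = as.integer(num_trees),
                 num_features = if (is.null(num_features)) NULL
                                else as.integer(num_features),
                 seed = as.integer(seed)),
            class = "rf_config")
}

#' Train a random-forest TSS classifier
#'
#' @param fm A [feature_matrix()] with both classes present.
#' @param cfg An [rf_config()].
#' @return A list of class `tss_rf_model` carrying the fitted forest, the
#'   feature-name manifest and the configuration.
#' @export
train_rf <- function(fm, cfg = rf_config()) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(unique(fm$labels)) < 2L)
    abort_validation("training data must contain both classes")
  d <- ncol(fm$values)
  mtry <- if (is.null(cfg$num_features)) ceiling(sqrt(d))
          else min(cfg$num_features, d)
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = fm$values, y = factor(fm$labels, levels = c(0L, 1L)),
    ntree = cfg$num_trees, mtry = mtry)
  structure(list(rf = rf, feature_names = fm$feature_names, config = cfg),
            class = "tss_rf_model")
}

#' Predict labels for new windows
#'
#' @param object A `tss_rf_model`.
#' @param newdata A [feature_matrix()] or numeric matrix whose columns are
#'   exactly the training features.
#' @param ... Unused.
#' @return Integer vector of 0/1 labels.
#' @export
predict.tss_rf_model <- function(object, newdata, ...) {
  vals <- if (inherits(newdata, "feature_matrix")) newdata$values
          else as.matrix(newdata)
  if (!setequal(colnames(vals), object$feature_names))
    abort_validation("prediction features do not match the training manifest")
  vals <- vals[, object$feature_names, drop = FALSE]
  as.integer(as.character(predict(object$rf, vals)))
}

#' Save / load a trained model with its feature manifest
#'
#' @param model A `tss_rf_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "tss_rf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tss_rf_model"))
    abort_validation("%s does not contain a tss_rf_model", path)
  model
}

# Stratified fold assignment: shuffle within each class, then deal folds
# cyclically over the class-ordered samples so class balance is as even as
# the counts allow (leave-one-out degenerates gracefully).
stratified_folds <- function(labels, folds) {
  assignment <- integer(length(labels))
  ordered <- unlist(lapply(c(1L, 0L), function(cl) sample(which(labels == cl))))
  assignment[ordered] <- rep_len(seq_len(folds), length(ordered))
  assignment
}

confusion_from_predictions <- function(truth, pred) {
  confusion_matrix(tp = sum(truth == 1L & pred == 1L),
                   tn = sum(truth == 0L & pred == 0L),
                   fp = sum(truth == 0L & pred == 1L),
                   fn = sum(truth == 1L & pred == 0L))
}

#' Repeated stratified cross-validation of the random forest
#'
#' Folds are stratified by class and re-randomised at each repeat from
#' `cfg$seed + repeat index`; the per-fold confusion matrices give the five
#' metrics, pooled over folds x repeats into a mean and standard deviation
#' per criterion.
#'
#' @param fm A [feature_matrix()].
#' @param folds Number of folds (>= 2).
#' @param repeats Number of independent repetitions.
#' @param cfg An [rf_config()].
#' @return A data frame of class `cv_report` with columns `criterion`
#'   (`Acc`, `Sn`, `Sp`, `Pr`, `MCC`), `mu` and `sigma`.
#' @export
cross_validate <- function(fm, folds = 5L, repeats = 10L, cfg = rf_config()) {
  stopifnot(inherits(fm, "feature_matrix"), folds >= 2L, repeats >= 1L)
  n <- nrow(fm$values)
  if (folds > n) abort_validation("more folds (%d) than samples (%d)", folds, n)
  if (min(table(factor(fm$labels, levels = c(0L, 1L)))) < 1L)
    abort_validation("both classes required for cross-validation")
  per_fold <- list()
  for (r in seq_len(repeats)) {
    set.seed(cfg$seed + r)
    assignment <- stratified_folds(fm$labels, folds)
    for (f in seq_len(folds)) {
      test <- assignment == f
      if (length(unique(fm$labels[!test])) < 2L)
        abort_validation("a class is too small for %d-fold stratification", folds)
      sub <- feature_matrix(fm$values[!test, , drop = FALSE],
                            fm$labels[!test])
      model <- train_rf(sub, rf_config(cfg$num_trees, cfg$num_features,
                                       seed = cfg$seed + 1000L * r + f))
      pred <- predict(model, fm$values[test, , drop = FALSE])
      m <- compute_metrics(confusion_from_predictions(fm$labels[test], pred))
      per_fold[[length(per_fold) + 1L]] <-
        c(Acc = m$acc, Sn = m$sn, Sp = m$sp, Pr = m$pr, MCC = m$mcc)
    }
  }
  tab <- do.call(rbind, per_fold)
  out <- data.frame(criterion = colnames(tab),
                    mu = colMeans(tab),
                    sigma = apply(tab, 2L, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, folds = folds, repeats = repeats,
            class = c("cv_report", "data.frame"))
}

#' Sensitivity scan over random-forest hyperparameters
#'
#' Cross-validates every combination of tree count and per-split feature
#' count, mirroring the usual sensitivity analysis used to fix `numTrees`
#' and `numFeatures`.
#'
#' @param fm A [feature_matrix()].
#' @param num_trees_grid,num_features_grid Candidate values.
#' @param folds,repeats,seed Cross-validation settings.
#' @return Data frame with one row per combination and the mean accuracy
#'   and MCC.
#' @export
rf_sensitivity_scan <- function(fm, num_trees_grid = c(50L, 100L, 200L),
                                num_features_grid = NULL,
                                folds = 5L, repeats = 2L, seed = 1L) {
  if (is.null(num_features_grid))
    num_features_grid <- unique(pmax(1L, round(sqrt(ncol(fm$values)) * c(.5, 1, 2))))
  grid <- expand.grid(num_trees = num_trees_grid,
                      num_features = num_features_grid)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cv <- cross_validate(fm, folds, repeats,
                         rf_config(grid$num_trees[i], grid$num_features[i], seed))
    data.frame(num_trees = grid$num_trees[i],
               num_features = grid$num_features[i],
               acc_mu = cv$mu[cv$criterion == "Acc"],
               mcc_mu = cv$mu[cv$criterion == "MCC"])
  })
  do.call(rbind, res)
}
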