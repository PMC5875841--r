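# Balanced, permuted, cross-validated RBF-SVM evaluation protocol.
#
# The cohort is imbalanced (more NBL than BL recordings), so the majority
# class is randomly undersampled to the minority size; because both the
# subsample and the row order influence 4-fold cross-validation, the
# protocol draws n_resamples balanced datasets and permutes each
# n_permutations times (default 10 x 10 = 100 runs). Every run evaluates a
# soft-margin SVM with Gaussian kernel exp(-gamma*||x-y||^2) over the full
# (gamma, C) grid under stratified 4-fold CV; overall accuracy, sensitivity
# and specificity are averaged per cell over all runs and the optimal cell
# maximizes mean overall accuracy. BL is the positive class throughout.

#' The gamma/C search grid
#'
#' gamma in {0.001, 0.005, 0.01, 0.05, 0.1, 0.15, 0.2} (7 values);
#' C in {0.01} union {1e, 2e, 5e : e = 10^0 .. 10^18} (58 values).
#'
#' @return An object of class `ppg_param_grid` with sorted `gamma` and `C`.
#' @export
build_param_grid <- function() {
  gamma <- c(0.001, 0.005, 0.01, 0.05, 0.1, 0.15, 0.2)
  C <- sort(unique(c(0.01, as.vector(outer(c(1, 2, 5), 10^(0:18))))))
  structure(list(gamma = gamma, C = C), class = "ppg_param_grid")
}

#' A reduced gamma/C grid for quick experiments
#'
#' Same 7 gamma values, C restricted to {0.01, 1, 2, 5, 10, 20, 50, 100}.
#'
#' @return A `ppg_param_grid`.
#' @export
reduced_param_grid <- function() {
  g <- build_param_grid()
  g$C <- c(0.01, 1, 2, 5, 10, 20, 50, 100)
  g
}

#' Balance a feature table by undersampling the majority class
#'
#' The majority class is subsampled uniformly without replacement to the
#' minority-class size; deterministic given `seed`.
#'
#' @param features feature table (see [read_features()]) with both classes.
#' @param seed integer seed for the subsample.
#' @return A feature table with equal class counts.
#' @export
balance_dataset <- function(features, seed) {
  features <- validate_features(as.data.frame(features))
  n_by <- table(factor(features$label, levels = c("BL", "NBL")))
  if (any(n_by == 0)) stopf("both classes must be present to balance")
  minority <- names(n_by)[which.min(n_by)]
  majority <- setdiff(c("BL", "NBL"), minority)
  m <- min(n_by)
  keep_maj <- with_seed(seed, sample(which(features$label == majority), m))
  out <- rbind(features[features$label == minority, , drop = FALSE],
               features[sort(keep_maj), , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Classification metrics from confusion counts
#'
#' BL is the positive class: sensitivity is the true-BL detection rate,
#' specificity the true-NBL rate; all in percent.
#'
#' @param tp,fn,tn,fp confusion counts.
#' @return Named vector: `oa`, `sensitivity`, `specificity` (percent).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  c(oa = 100 * (tp + tn) / (tp + fn + tn + fp),
    sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp))
}

FEATURE_NUM_COLS <- c("r2", "slope", "pct_change", "abs_change")

# Stratified fold assignment from the dataset's current row order:
# within each class, rows get folds 1..k round-robin by position, so the
# assignment is deterministic given the (already permuted) order.
stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

svm_fold_counts <- function(X, y, fold, n_folds, gamma, C, scaling) {
  counts <- c(tp = 0, fn = 0, tn = 0, fp = 0)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    if (all(tr)) next  # fewer records than folds: this fold tests nothing
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (scaling == "standardize") {
      mu <- colMeans(Xtr)
      sd <- apply(Xtr, 2, stats::sd)
      sd[sd == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sd, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sd, "/")
    }
    fit <- e1071::svm(Xtr, y[tr], kernel = "radial", gamma = gamma, cost = C,
                      scale = FALSE)
    pred <- predict(fit, Xte)
    truth <- y[!tr]
    counts["tp"] <- counts["tp"] + sum(pred == "BL" & truth == "BL")
    counts["fn"] <- counts["fn"] + sum(pred == "NBL" & truth == "BL")
    counts["tn"] <- counts["tn"] + sum(pred == "NBL" & truth == "NBL")
    counts["fp"] <- counts["fp"] + sum(pred == "BL" & truth == "NBL")
  }
  counts
}

#' One stratified k-fold CV evaluation of an RBF-SVM
#'
#' Partitions the dataset into stratified folds (each record tested exactly
#' once), trains `e1071::svm` with the Gaussian kernel on the remaining
#' folds and accumulates confusion counts over held-out predictions.
#'
#' @param dataset balanced feature table with both classes.
#' @param gamma,C RBF-SVM hyperparameters.
#' @param n_folds number of CV folds (default 4).
#' @param seed seed for the row permutation that determines folds.
#' @param scaling `"none"` (default) or `"standardize"` (training-fold
#'   statistics only).
#' @return List with `counts` (tp/fn/tn/fp) and `metrics` (percent).
#' @export
run_cv <- function(dataset, gamma, C, n_folds = 4, seed = 1,
                   scaling = c("none", "standardize")) {
  scaling <- match.arg(scaling)
  dataset <- validate_features(as.data.frame(dataset))
  X <- as.matrix(dataset[, FEATURE_NUM_COLS])
  if (any(!is.finite(X))) stopf("non-finite feature values")
  y <- factor(dataset$label, levels = c("BL", "NBL"))
  ord <- with_seed(seed, sample(nrow(dataset)))
  fold <- integer(nrow(dataset))
  fold[ord] <- stratified_folds(y[ord], n_folds)
  counts <- svm_fold_counts(X, y, fold, n_folds, gamma, C, scaling)
  list(counts = counts,
       metrics = confusion_metrics(counts["tp"], counts["fn"],
                                   counts["tn"], counts["fp"]))
}

#' Experiment configuration for the full evaluation protocol
#'
#' @param n_resamples number of balanced datasets drawn (default 10).
#' @param n_permutations row-order permutations per dataset (default 10).
#' @param n_folds CV folds (default 4).
#' @param seed master seed; all sub-seeds derive from it.
#' @param scaling `"none"` or `"standardize"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_resamples = 10, n_permutations = 10,
                              n_folds = 4, seed = 1,
                              scaling = c("none", "standardize")) {
  scaling <- match.arg(scaling)
  if (n_folds < 2) stopf("n_folds must be >= 2")
  structure(list(n_resamples = as.integer(n_resamples),
                 n_permutations = as.integer(n_permutations),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 scaling = scaling),
            class = "experiment_config")
}

#' Run the full balanced/permuted/cross-validated grid-search experiment
#'
#' For each of `n_resamples` balanced datasets and `n_permutations` row
#' orders (sub-seeds derived deterministically from the master seed), every
#' (gamma, C) cell is evaluated by stratified `n_folds`-fold CV; overall
#' accuracy, sensitivity and specificity are averaged per cell over all
#' `n_resamples * n_permutations` runs. The optimal cell maximizes mean
#' overall accuracy, with ties broken by smaller C then smaller gamma.
#'
#' @param features feature table containing both classes.
#' @param config an [experiment_config()].
#' @param grid a `ppg_param_grid` (default [build_param_grid()]).
#' @return An object of class `ppg_experiment`: mean metric matrices
#'   (`gamma` x `C`), the per-run per-cell confusion-count array for audit,
#'   and the optimal cell.
#' @export
run_experiment <- function(features, config = experiment_config(),
                           grid = build_param_grid()) {
  features <- validate_features(as.data.frame(features))
  ng <- length(grid$gamma)
  nc <- length(grid$C)
  n_runs <- config$n_resamples * config$n_permutations
  oa <- sens <- spec <- array(NA_real_, c(ng, nc, n_runs))
  counts <- array(0L, c(ng, nc, n_runs, 4),
                  dimnames = list(NULL, NULL, NULL, c("tp", "fn", "tn", "fp")))
  run <- 0L
  for (r in seq_len(config$n_resamples)) {
    bal <- balance_dataset(features, seed = config$seed + 1000L * r)
    y_all <- factor(bal$label, levels = c("BL", "NBL"))
    X_all <- as.matrix(bal[, FEATURE_NUM_COLS])
    for (p in seq_len(config$n_permutations)) {
      run <- run + 1L
      ord <- with_seed(config$seed + 1000L * r + p, sample(nrow(bal)))
      fold <- integer(nrow(bal))
      fold[ord] <- stratified_folds(y_all[ord], config$n_folds)
      for (gi in seq_len(ng)) for (ci in seq_len(nc)) {
        cnt <- svm_fold_counts(X_all, y_all, fold, config$n_folds,
                               grid$gamma[gi], grid$C[ci], config$scaling)
        counts[gi, ci, run, ] <- cnt
        m <- confusion_metrics(cnt["tp"], cnt["fn"], cnt["tn"], cnt["fp"])
        oa[gi, ci, run] <- m["oa"]
        sens[gi, ci, run] <- m["sensitivity"]
        spec[gi, ci, run] <- m["specificity"]
      }
    }
  }
  mean_oa <- apply(oa, c(1, 2), mean)
  mean_sens <- apply(sens, c(1, 2), mean)
  mean_spec <- apply(spec, c(1, 2), mean)
  dimnames(mean_oa) <- dimnames(mean_sens) <- dimnames(mean_spec) <-
    list(gamma = format(grid$gamma), C = format(grid$C, scientific = TRUE))
  # optimal cell: max mean OA; ties -> smaller C, then smaller gamma
  best <- c(1L, 1L)
  for (ci in seq_len(nc)) for (gi in seq_len(ng))
    if (mean_oa[gi, ci] > mean_oa[best[1], best[2]] + 1e-12) best <- c(gi, ci)
  structure(list(mean_oa = mean_oa, mean_sensitivity = mean_sens,
                 mean_specificity = mean_spec, counts = counts,
                 grid = grid, config = config, n_runs = n_runs,
                 optimal = list(gamma = grid$gamma[best[1]], C = grid$C[best[2]],
                                gamma_index = best[1], C_index = best[2],
                                oa = mean_oa[best[1], best[2]],
                                sensitivity = mean_sens[best[1], best[2]],
                                specificity = mean_spec[best[1], best[2]])),
            class = "ppg_experiment")
}

#' Column-normalized confusion matrix (percent) for an experiment cell
#'
#' Rows Predicted BL / Predicted NBL, columns True BL / True NBL; each
#' column sums to 100. The diagonal holds sensitivity and specificity.
#'
#' @param result a `ppg_experiment`.
#' @param gamma_index,C_index grid cell (default: the optimal cell).
#' @return A 2x2 matrix of percentages.
#' @export
confusion_table <- function(result, gamma_index = result$optimal$gamma_index,
                            C_index = result$optimal$C_index) {
  sens <- result$mean_sensitivity[gamma_index, C_index]
  spec <- result$mean_specificity[gamma_index, C_index]
  matrix(c(sens, 100 - sens, 100 - spec, spec), nrow = 2,
         dimnames = list(c("Predicted BL", "Predicted NBL"),
                         c("True BL", "True NBL")))
}

#' @export
print.ppg_experiment <- function(x, ...) {
  cat(sprintf("RBF-SVM grid-search experiment: %d x %d grid, %d runs/cell (%d resamples x %d permutations, %d-fold CV, scaling: %s)\n",
              length(x$grid$gamma), length(x$grid$C), x$n_runs,
              x$config$n_resamples, x$config$n_permutations,
              x$config$n_folds, x$config$scaling))
  cat(sprintf("optimal cell: gamma = %g, C = %g -> OA %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
              x$optimal$gamma, x$optimal$C, x$optimal$oa,
              x$optimal$sensitivity, x$optimal$specificity))
  invisible(x)
}

#' @export
summary.ppg_experiment <- function(object, ...) {
  print(object)
  cat("\nConfusion matrix at the optimal cell (column percentages; diagonal = sensitivity, specificity):\n")
  print(round(confusion_table(object), 2))
  invisible(object)
}

#' Write an experiment result to JSON
#'
#' Emits the per-cell mean metrics, the optimal cell, the experiment
#' configuration and the optimal-cell confusion table; round-trips through
#' [jsonlite::read_json()].
#'
#' @param result a `ppg_experiment`.
#' @param path output JSON path.
#' @return The path, invisibly.
#' @export
report_experiment <- function(result, path) {
  stopifnot(inherits(result, "ppg_experiment"))
  out <- list(
    grid = list(gamma = result$grid$gamma, C = result$grid$C),
    config = unclass(result$config),
    n_runs = result$n_runs,
    optimal = result$optimal[c("gamma", "C", "oa", "sensitivity", "specificity")],
    mean_oa = unname(result$mean_oa),
    mean_sensitivity = unname(result$mean_sensitivity),
    mean_specificity = unname(result$mean_specificity),
    confusion_pct = unname(confusion_table(result)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
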