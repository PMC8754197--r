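#' Default gradient-boosting hyperparameters
#'
#' Learning rate 0.1 (the published configuration); the remaining values
#' (150 rounds, depth 6, no subsampling) are package defaults exposed here
#' so any of them can be overridden via the `params` argument of the
#' training and evaluation functions. `nthread = 1` keeps training bitwise
#' reproducible.
#'
#' @return Named list of defaults.
#' @export
default_xgb_params <- function() {
  list(eta = 0.1, nrounds = 150L, max_depth = 6L, subsample = 1,
       colsample_bytree = 1, nthread = 1L, seed = 1L)
}

.merge_params <- function(params) {
  out <- default_xgb_params()
  for (nm in names(params)) out[[nm]] <- params[[nm]]
  out
}

.as_feature_matrix <- function(x) {
  if (is.matrix(x)) x else feature_matrix(x)
}

#' Train the SAV pathogenicity classifier
#'
#' Fits a binary XGBoost tree ensemble (logistic objective) on an imputed
#' feature matrix. Training is deterministic for a fixed seed.
#'
#' @param x Feature matrix or `sav_features` data.frame, no missing cells.
#' @param labels 0/1 pathogenicity labels (both classes required).
#' @param params Hyperparameter overrides, see [default_xgb_params()].
#' @return A `sav_model`: list with the fitted `booster`, `features` (column
#'   order), `params`, and per-feature `importance` (gain; 0 for features
#'   never used in a split).
#' @export
train_sav_classifier <- function(x, labels, params = list()) {
  m <- .as_feature_matrix(x)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  if (anyNA(m))
    stop("missing feature cells: impute before training", call. = FALSE)
  p <- .merge_params(params)
  dtrain <- xgboost::xgb.DMatrix(m, label = labels, nthread = p$nthread)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = p$eta,
                  max_depth = p$max_depth, subsample = p$subsample,
                  colsample_bytree = p$colsample_bytree,
                  nthread = p$nthread, seed = p$seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0)
  imp <- stats::setNames(rep(0, ncol(m)), colnames(m))
  tab <- xgboost::xgb.importance(model = booster)
  imp[tab$Feature] <- tab$Gain
  structure(list(booster = booster, features = colnames(m), params = p,
                 importance = imp),
            class = "sav_model")
}

#' Predicted pathogenicity probabilities and classes
#'
#' Probabilities come from the fitted ensemble; the hard class is 1 when the
#' probability is strictly greater than 0.5.
#'
#' @param model A [train_sav_classifier()] model.
#' @param x Feature matrix/table with the same columns as at training.
#' @param type `"prob"` for probabilities in [0, 1], `"class"` for 0/1.
#' @return Numeric (prob) or integer (class) vector, one value per row.
#' @export
predict_sav <- function(model, x, type = c("prob", "class")) {
  type <- match.arg(type)
  stopifnot(inherits(model, "sav_model"))
  m <- .as_feature_matrix(x)
  if (!identical(colnames(m), model$features))
    stop("feature columns do not match the trained model (expected ",
         paste(model$features, collapse = ", "), ")", call. = FALSE)
  p <- predict(model$booster, xgboost::xgb.DMatrix(m, nthread = model$params$nthread))
  if (type == "prob") p else as.integer(p > 0.5)
}

#' @export
print.sav_model <- function(x, ...) {
  cat(sprintf("SAV classifier: %d features, eta %.3g, %d rounds, depth %d\n",
              length(x$features), x$params$eta, x$params$nrounds,
              x$params$max_depth))
  invisible(x)
}

#' Deterministic stratified fold assignment
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return Integer fold id (1..k) per row; per-fold class proportions are
#'   within one sample of the global proportions.
#' @export
stratified_folds <- function(labels, k, seed) {
  labels <- as.integer(labels)
  if (k > min(table(labels)))
    stop("k exceeds the size of the smallest class", call. = FALSE)
  fold <- integer(length(labels))
  set.seed(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Ten-fold (by default) stratified CV: fold assignment is a deterministic
#' function of the seed; within each fold, median imputation is refit on the
#' training rows only, the model is trained on the training rows and scored
#' on the held-out rows. Reports per-fold metrics, their mean and standard
#' deviation, per-fold AUROC/AUPR, and pooled ROC/PR curves over all
#' held-out scores.
#'
#' @param x `sav_features` data.frame or feature matrix (may contain NAs;
#'   they are imputed per training fold).
#' @param labels 0/1 labels.
#' @param k Number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and training.
#' @param params Hyperparameter overrides, see [default_xgb_params()].
#' @return A `cv_result`: `per_fold` data.frame (fold, accuracy, sensitivity,
#'   specificity, f1, mcc, balanced_accuracy, auroc, aupr), `mean`, `sd`,
#'   `pooled` ([roc_pr()] over pooled held-out scores), `folds`, `scores`
#'   (held-out probability per row).
#' @export
kfold_cv <- function(x, labels, k = 10L, seed = 1L, params = list()) {
  labels <- as.integer(labels)
  df <- if (is.matrix(x)) as.data.frame(x) else x
  fold <- stratified_folds(labels, k, seed)
  metric_names <- c("accuracy", "sensitivity", "specificity", "f1", "mcc",
                    "balanced_accuracy")
  per_fold <- data.frame(fold = seq_len(k))
  for (nm in c(metric_names, "auroc", "aupr")) per_fold[[nm]] <- NA_real_
  scores <- numeric(length(labels))
  p <- .merge_params(params)
  has_na <- anyNA(feature_matrix(df))
  for (f in seq_len(k)) {
    train_rows <- fold != f
    xi <- if (has_na) impute_features(df, which(train_rows)) else df
    model <- train_sav_classifier(feature_matrix(xi)[train_rows, , drop = FALSE],
                                  labels[train_rows],
                                  c(p[setdiff(names(p), "seed")],
                                    list(seed = p$seed + f)))
    prob <- predict_sav(model, feature_matrix(xi)[!train_rows, , drop = FALSE])
    scores[!train_rows] <- prob
    mr <- classification_metrics(confusion_counts(labels[!train_rows],
                                                  as.integer(prob > 0.5)))
    for (nm in metric_names) per_fold[[nm]][f] <- mr[[nm]]
    curves <- roc_pr(labels[!train_rows], prob)
    per_fold$auroc[f] <- curves$auroc
    per_fold$aupr[f] <- curves$aupr
  }
  cols <- setdiff(names(per_fold), "fold")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[cols]),
                 sd = apply(per_fold[cols], 2L, stats::sd),
                 pooled = roc_pr(labels, scores),
                 folds = fold, scores = scores, k = k, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: accuracy %.4f±%.4f, AUROC %.4f±%.4f, AUPR %.4f±%.4f\n",
              x$k, x$mean[["accuracy"]], x$sd[["accuracy"]],
              x$mean[["auroc"]], x$sd[["auroc"]],
              x$mean[["aupr"]], x$sd[["aupr"]]))
  invisible(x)
}

#' Leave-one-feature-out ablation
#'
#' Retrains and cross-validates the classifier once per feature with that
#' feature excluded (14 features per run), reporting accuracy, balanced
#' accuracy and F1 per exclusion, sorted by accuracy drop relative to the
#' full model.
#'
#' @inheritParams kfold_cv
#' @return data.frame: excluded_feature, accuracy, balanced_accuracy, f1,
#'   accuracy_drop; attribute `full` holds the full-model CV means.
#' @export
ablation <- function(x, labels, k = 10L, seed = 1L, params = list()) {
  df <- if (is.matrix(x)) as.data.frame(x) else x
  feats <- intersect(feature_names(), colnames(df))
  full <- kfold_cv(df, labels, k = k, seed = seed, params = params)
  rows <- lapply(feats, function(feat) {
    cv <- kfold_cv(df[, setdiff(names(df), feat), drop = FALSE], labels,
                   k = k, seed = seed, params = params)
    data.frame(excluded_feature = feat,
               accuracy = cv$mean[["accuracy"]],
               balanced_accuracy = cv$mean[["balanced_accuracy"]],
               f1 = cv$mean[["f1"]])
  })
  out <- do.call(rbind, rows)
  out$accuracy_drop <- full$mean[["accuracy"]] - out$accuracy
  out <- out[order(-out$accuracy_drop), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "full") <- full$mean
  out
}

#' Accuracy stratified by ortholog count
#'
#' For each ortholog-count threshold, cross-validated accuracy where each
#' fold's training rows are restricted to SAVs of proteins with at least that
#' many orthologous sequences, while every fold is still evaluated on its
#' full held-out rows — the leakage-free analogue of training on the stratum
#' and testing on the whole dataset.
#'
#' @inheritParams kfold_cv
#' @param ortholog_counts Per-row ortholog count of the SAV's protein.
#' @param thresholds Minimum ortholog counts to stratify by.
#' @return data.frame: threshold, n_train (stratum size), accuracy, auroc.
#'   Strata that lose a class entirely are skipped with a warning.
#' @export
stratify_by_orthologs <- function(x, labels, ortholog_counts,
                                  thresholds = c(50, 100, 150, 200, 250, 300),
                                  k = 10L, seed = 1L, params = list()) {
  labels <- as.integer(labels)
  stopifnot(length(ortholog_counts) == length(labels))
  df <- if (is.matrix(x)) as.data.frame(x) else x
  fold <- stratified_folds(labels, k, seed)
  out <- lapply(thresholds, function(th) {
    stratum <- ortholog_counts >= th
    if (length(unique(labels[stratum])) < 2L) {
      warning("stratum >= ", th, " orthologs lacks a class; skipped",
              call. = FALSE)
      return(NULL)
    }
    scores <- numeric(length(labels))
    for (f in seq_len(k)) {
      train_rows <- fold != f & stratum
      if (length(unique(labels[train_rows])) < 2L) {
        warning("fold ", f, " at threshold ", th, " lacks a class; skipped",
                call. = FALSE)
        return(NULL)
      }
      xi <- if (anyNA(feature_matrix(df))) impute_features(df, which(train_rows)) else df
      model <- train_sav_classifier(feature_matrix(xi)[train_rows, , drop = FALSE],
                                    labels[train_rows],
                                    c(params[setdiff(names(params), "seed")],
                                      list(seed = seed + f)))
      scores[fold == f] <- predict_sav(model,
                                       feature_matrix(xi)[fold == f, , drop = FALSE])
    }
    mr <- classification_metrics(confusion_counts(labels, as.integer(scores > 0.5)))
    data.frame(threshold = th, n_train = sum(stratum),
               accuracy = mr$accuracy, auroc = roc_pr(labels, scores)$auroc)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Benchmark predictions against a deep mutational scanning dataset
#'
#' Merges predicted pathogenicity scores with experimental DMS fitness
#' scores on the shared variants and reports the absolute Spearman rank
#' correlation (average-rank tie handling), the mean squared error, and the
#' prediction coverage (shared variants / DMS variants). Constant
#' predictions leave the rank correlation undefined; it is reported as 0
#' with `rho_defined = FALSE` while the MSE is still computed.
#'
#' @param predictions data.frame with key columns (`protein_id`, `position`,
#'   `wt_aa`, `mut_aa`, or a `variant` string) and a `prediction` column.
#' @param dms_scores data.frame with the same key columns and a `dms_score`
#'   column.
#' @return A `benchmark_report`: list with `spearman` (absolute rho), `mse`,
#'   `coverage`, `n_shared`, `rho_defined`.
#' @export
benchmark_dms <- function(predictions, dms_scores) {
  key_cols <- intersect(c("protein_id", "variant", "position", "wt_aa", "mut_aa"),
                        intersect(names(predictions), names(dms_scores)))
  if (length(key_cols) == 0L)
    stop("no shared key columns between predictions and DMS table", call. = FALSE)
  merged <- merge(predictions[, c(key_cols, "prediction")],
                  dms_scores[, c(key_cols, "dms_score")], by = key_cols)
  if (nrow(merged) < 3L)
    stop("fewer than 3 shared variants between predictions and DMS table",
         call. = FALSE)
  rho_defined <- stats::sd(merged$prediction) > 0 && stats::sd(merged$dms_score) > 0
  rho <- if (rho_defined)
    abs(stats::cor(merged$prediction, merged$dms_score, method = "spearman"))
  else 0
  structure(list(spearman = rho,
                 mse = mean((merged$prediction - merged$dms_score)^2),
                 coverage = nrow(merged) / nrow(dms_scores),
                 n_shared = nrow(merged),
                 rho_defined = rho_defined),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("DMS benchmark: |Spearman rho| %.4f%s, MSE %.4f, coverage %.1f%% (%d variants)\n",
              x$spearman, if (x$rho_defined) "" else " (undefined -> 0)",
              x$mse, 100 * x$coverage, x$n_shared))
  invisible(x)
}
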