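#' Train the nucleosomal-vs-linker random forest
#'
#' Fits a random forest on a labeled spectral feature table, mirroring the
#' canonical setup: 500 trees, `floor(sqrt(288)) = 16` candidate features per
#' split, unlimited depth, no class weighting. Label 1 is nucleosomal, 0 is
#' linker. Training is deterministic for a fixed `seed`.
#'
#' @param data A tibble as produced by [featurize_set()] with a binary `label`
#'   column (1 = nucleosomal, 0 = linker), the 288 feature columns, and
#'   optionally `id`.
#' @param n_trees Number of trees (default 500).
#' @param seed Integer seed controlling the forest's randomness.
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @return An object of class `nf_model` wrapping the fitted
#'   `randomForest::randomForest` ensemble plus training metadata
#'   (`n_trees`, `mtry`, `seed`, `n_train`, `train_fingerprint`).
#' @seealso [nf_predict()], [feature_importance()], [cross_validate()]
#' @export
nf_train <- function(data, n_trees = 500, seed = 1L, mtry = NULL) {
  xy <- check_labeled_set(data, require_both_classes = TRUE)
  if (n_trees < 1) stop("n_trees must be >= 1", call. = FALSE)
  mtry <- mtry %||% floor(sqrt(ncol(xy$x)))
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(
    x = xy$x, y = xy$y, ntree = as.integer(n_trees), mtry = mtry
  )
  structure(
    list(
      forest = fit,
      feature_names = colnames(xy$x),
      n_trees = as.integer(n_trees),
      mtry = mtry,
      seed = as.integer(seed),
      n_train = nrow(xy$x),
      class_counts = table(xy$y),
      train_fingerprint = dataset_fingerprint(xy$x, xy$labels)
    ),
    class = "nf_model"
  )
}

#' @export
print.nf_model <- function(x, ...) {
  cat("<nf_model> random forest:", x$n_trees, "trees, mtry =", x$mtry,
      "\n  trained on", x$n_train, "sequences (",
      paste(names(x$class_counts), unclass(x$class_counts),
            sep = "=", collapse = ", "),
      "), seed", x$seed, "\n")
  invisible(x)
}

check_labeled_set <- function(data, require_both_classes = FALSE) {
  stopifnot(is.data.frame(data))
  fn <- nf_feature_names()
  missing <- setdiff(fn, names(data))
  if (length(missing) > 0L) {
    stop("feature column(s) missing from data, e.g. ", missing[1L],
         call. = FALSE)
  }
  x <- as.matrix(data[, fn])
  if (anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix contains missing or non-finite values", call. = FALSE)
  }
  labels <- NULL
  y <- NULL
  if ("label" %in% names(data)) {
    labels <- data$label
    if (!all(labels %in% c(0, 1))) {
      stop("labels must be 0 (linker) or 1 (nucleosomal)", call. = FALSE)
    }
    if (require_both_classes && length(unique(labels)) < 2L) {
      stop("single-class training set: both nucleosomal (1) and linker (0) ",
           "examples are required", call. = FALSE)
    }
    y <- factor(ifelse(labels == 1, "nucleosomal", "linker"),
                levels = c("linker", "nucleosomal"))
  } else if (require_both_classes) {
    stop("training data must have a `label` column", call. = FALSE)
  }
  list(x = x, y = y, labels = labels,
       ids = if ("id" %in% names(data)) as.character(data$id)
             else as.character(seq_len(nrow(data))))
}

dataset_fingerprint <- function(x, labels) {
  v <- c(dim(x), round(sum(x), 6), round(sum(labels), 6))
  paste(format(v, scientific = FALSE, trim = TRUE), collapse = ":")
}

#' Predict nucleosomal vs linker
#'
#' @param model An [nf_model][nf_train].
#' @param features A tibble with the model's 288 feature columns (and
#'   optionally `id`), e.g. from [featurize_set()].
#' @return A tibble with `id`, `prob` (fraction of trees voting nucleosomal)
#'   and `label` (1 if `prob >= 0.5`; a tie at exactly 0.5 is called
#'   nucleosomal).
#' @export
nf_predict <- function(model, features) {
  stopifnot(inherits(model, "nf_model"))
  xy <- check_labeled_set(features)
  if (!identical(colnames(xy$x), model$feature_names)) {
    stop("feature names do not match the model's training features",
         call. = FALSE)
  }
  prob <- unname(stats::predict(model$forest, xy$x, type = "prob")[, "nucleosomal"])
  tibble::tibble(id = xy$ids, prob = prob, label = as.integer(prob >= 0.5))
}

#' Gini feature importance
#'
#' Mean decrease in Gini impurity attributable to each spectral feature across
#' the ensemble, sorted descending (ties broken by feature name).
#'
#' @param model An [nf_model][nf_train].
#' @return A tibble with columns `feature`, `shape`, `freq_index`,
#'   `importance`, one row per model feature.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "nf_model"))
  imp <- model$forest$importance[, "MeanDecreaseGini"]
  out <- tibble::tibble(
    feature = names(imp),
    importance = unname(imp)
  )
  out <- dplyr::left_join(
    out,
    tibble::tibble(feature = nf_feature_names(),
                   shape = rep(shape_channel_names(), each = 72L),
                   freq_index = rep(1:72, 4L)),
    by = "feature"
  )
  dplyr::arrange(out[, c("feature", "shape", "freq_index", "importance")],
                 dplyr::desc(.data$importance), .data$feature)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Assigns stratified folds from `seed`, trains one forest per fold, and
#' scores the held-out examples. Reports the six standard metrics (accuracy,
#' sensitivity, specificity, F1, AUC, MCC) as mean and SD over folds, plus the
#' pooled confusion counts.
#'
#' @param data Labeled feature tibble (see [nf_train()]).
#' @param k Number of folds (>= 2; each class must have at least `k` members).
#' @param seed Integer seed for fold assignment and per-fold training.
#' @param n_trees,mtry Forest parameters, as in [nf_train()].
#' @return An object of class `nf_cv`: a list with `summary` (tibble
#'   `metric`, `mean`, `sd`), `folds` (per-fold metric tibble), `confusion`
#'   (pooled TP/FP/TN/FN), `predictions` (per-example out-of-fold `prob`,
#'   `label`, `truth`, `fold`), and the run parameters.
#' @export
cross_validate <- function(data, k = 10, seed = 1L, n_trees = 500, mtry = NULL) {
  xy <- check_labeled_set(data, require_both_classes = TRUE)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  cls_n <- table(xy$labels)
  if (any(cls_n < k)) {
    stop("each class needs at least k = ", k, " members; got ",
         paste(names(cls_n), cls_n, sep = "=", collapse = ", "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  fold <- integer(length(xy$labels))
  for (cl in unique(xy$labels)) {
    idx <- sample(which(xy$labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train_i <- fold != f
    set.seed(as.integer(seed) + f)
    fit <- randomForest::randomForest(
      x = xy$x[train_i, , drop = FALSE], y = xy$y[train_i],
      ntree = as.integer(n_trees),
      mtry = mtry %||% floor(sqrt(ncol(xy$x)))
    )
    p <- unname(stats::predict(fit, xy$x[!train_i, , drop = FALSE],
                               type = "prob")[, "nucleosomal"])
    preds[[f]] <- tibble::tibble(
      id = xy$ids[!train_i], fold = f, prob = p,
      label = as.integer(p >= 0.5), truth = xy$labels[!train_i]
    )
  }
  preds <- dplyr::bind_rows(preds)
  per_fold <- dplyr::group_modify(
    dplyr::group_by(preds, .data$fold),
    function(d, g) metrics_from_predictions(d$truth, d$label, d$prob)
  )
  per_fold <- tidyr::pivot_wider(per_fold, names_from = "metric",
                                 values_from = "value")
  metric_names <- c("accuracy", "sensitivity", "specificity", "F1", "AUC", "MCC")
  summary <- tibble::tibble(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(per_fold[[m]]), 0),
    sd = vapply(metric_names, function(m) stats::sd(per_fold[[m]]), 0)
  )
  confusion <- confusion_counts(preds$truth, preds$label)
  structure(
    list(summary = summary, folds = per_fold, confusion = confusion,
         predictions = preds, k = k, seed = as.integer(seed),
         n_trees = as.integer(n_trees)),
    class = "nf_cv"
  )
}

#' @export
print.nf_cv <- function(x, ...) {
  cat("<nf_cv>", x$k, "fold cross-validation,", x$n_trees,
      "trees, seed", x$seed, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %6.4f (+/- %.4f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
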