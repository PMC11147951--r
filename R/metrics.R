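#' Binary classification metrics from confusion counts and scores
#'
#' Computes the standard metric suite for a nucleosomal (positive) vs linker
#' (negative) classifier: accuracy, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, F1 `2TP/(2TP+FP+FN)`, MCC (0 substituted when any denominator
#' factor is 0), and — when scores are supplied — AUC by the rank method: the
#' probability that a random positive scores above a random negative, ties
#' counting one half.
#'
#' @param tp,fp,tn,fn Confusion counts (non-negative, total > 0).
#' @param scores Optional per-example probabilities for the AUC.
#' @param labels Truth labels (0/1) aligned with `scores`; required with
#'   `scores`.
#' @return A tibble with columns `metric` and `value`.
#' @export
compute_metrics <- function(tp, fp, tn, fn, scores = NULL, labels = NULL) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("confusion counts sum to zero", call. = FALSE)
  out <- tibble::tibble(
    metric = c("accuracy", "sensitivity", "specificity", "F1"),
    value = c(
      (tp + tn) / total,
      safe_div(tp, tp + fn),
      safe_div(tn, tn + fp),
      safe_div(2 * tp, 2 * tp + fp + fn)
    )
  )
  if (!is.null(scores)) {
    if (is.null(labels) || length(labels) != length(scores)) {
      stop("labels (0/1) of the same length as scores are required for AUC",
           call. = FALSE)
    }
    out <- dplyr::bind_rows(
      out, tibble::tibble(metric = "AUC", value = rank_auc(scores, labels))
    )
  }
  dplyr::bind_rows(
    out, tibble::tibble(metric = "MCC", value = mcc(tp, fp, tn, fn))
  )
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Matthews correlation coefficient
#' @param tp,fp,tn,fn Confusion counts.
#' @return MCC in `[-1, 1]`; 0 if any denominator factor is 0.
#' @export
mcc <- function(tp, fp, tn, fn) {
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Rank-based AUC
#'
#' Probability that a positive example outscores a negative one, ties counted
#' one half (equivalent to the Mann-Whitney U statistic normalised by
#' `n_pos * n_neg`).
#'
#' @param scores Numeric scores, higher = more positive.
#' @param labels Truth labels in `{0, 1}`.
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC requires both positive and negative examples", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

confusion_counts <- function(truth, label) {
  tibble::tibble(
    tp = sum(truth == 1 & label == 1),
    fp = sum(truth == 0 & label == 1),
    tn = sum(truth == 0 & label == 0),
    fn = sum(truth == 1 & label == 0)
  )
}

metrics_from_predictions <- function(truth, label, prob) {
  cc <- confusion_counts(truth, label)
  compute_metrics(cc$tp, cc$fp, cc$tn, cc$fn, scores = prob, labels = truth)
}
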