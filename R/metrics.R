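#' Area under the ROC curve
#'
#' Exact rank (Mann-Whitney) statistic with midrank handling of ties:
#' the probability that a random positive outscores a random negative.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels in `{0, 1}`; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop_format("AUROC undefined: only one class present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average precision: the recall-weighted sum of precision over score
#' thresholds, with tied scores handled as one threshold group.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  if (n1 == 0L) stop_format("AUPRC undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- which(diff(sc) != 0)
  grp_end <- c(grp_end, length(sc))
  tp <- cumsum(lab)[grp_end]
  n_pred <- grp_end
  prec <- tp / n_pred
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Youden-index optimal threshold
#'
#' Scans the observed score cut-points (predict positive when
#' `score >= threshold`) and returns the threshold maximizing
#' `J = sensitivity + specificity - 1`; ties break toward the lower
#' threshold.
#'
#' @inheritParams auroc
#' @return the optimal threshold.
#' @export
youden_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) {
    stop_format("Youden threshold undefined: only one class present")
  }
  cuts <- sort(unique(scores))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  j <- vapply(cuts, function(t) {
    pred <- scores >= t
    sum(pred & labels == 1L) / n1 + sum(!pred & labels == 0L) / n0 - 1
  }, numeric(1))
  cuts[which.max(j)]  # which.max takes the first (lowest) maximizer
}

#' Classification metrics at a Youden-calibrated threshold
#'
#' AUROC and AUPRC from the raw scores; accuracy, sensitivity and
#' specificity at the Youden threshold fitted on a calibration score set
#' (the validation split by convention).
#'
#' @param scores,labels test scores and labels.
#' @param calibration_scores,calibration_labels scores and labels used to
#'   fit the threshold; defaults to the test scores themselves.
#' @return a `tapb_metrics` list with `auroc`, `auprc`, `accuracy`,
#'   `sensitivity`, `specificity`, `threshold`.
#' @export
classification_metrics <- function(scores, labels,
                                   calibration_scores = scores,
                                   calibration_labels = labels) {
  labels <- as.integer(labels)
  thr <- youden_threshold(calibration_scores, calibration_labels)
  pred <- as.integer(scores >= thr)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  structure(list(
    auroc = auroc(scores, labels),
    auprc = auprc(scores, labels),
    accuracy = mean(pred == labels),
    sensitivity = if (n1) sum(pred == 1L & labels == 1L) / n1 else NA_real_,
    specificity = if (n0) sum(pred == 0L & labels == 0L) / n0 else NA_real_,
    threshold = thr
  ), class = "tapb_metrics")
}

#' @export
print.tapb_metrics <- function(x, ...) {
  cat(sprintf(
    "AUROC %.4f | AUPRC %.4f | acc %.4f | sens %.4f | spec %.4f (thr %.4f)\n",
    x$auroc, x$auprc, x$accuracy, x$sensitivity, x$specificity, x$threshold))
  invisible(x)
}

#' Aggregate metrics across seeds
#'
#' Reports mean and standard deviation per metric together with all
#' per-seed values (no silent averaging).
#'
#' @param metrics_list list of `tapb_metrics`, one per seed.
#' @return data.frame with one row per metric: mean, sd, and per-seed values.
#' @export
aggregate_metrics <- function(metrics_list) {
  fields <- c("auroc", "auprc", "accuracy", "sensitivity", "specificity")
  vals <- sapply(metrics_list, function(m) unlist(m[fields]))
  out <- data.frame(metric = fields,
                    mean = rowMeans(vals),
                    sd = apply(vals, 1L, stats::sd))
  per_seed <- as.data.frame(t(vals))
  rownames(per_seed) <- NULL
  names(per_seed) <- fields
  attr(out, "per_seed") <- per_seed
  out
}
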