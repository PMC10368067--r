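# Evaluation metrics: classification accuracy/sensitivity/specificity on
# confusion counts, and point-annotation detection scoring (precision,
# recall, F1) where ground truth is a set of points and predictions are
# labeled masks or rasterized boxes.

#' Classification metrics from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#' A metric whose denominator is zero is reported as `NA` (undefined), not
#' silently 0.
#'
#' @param tp,tn,fp,fn non-negative integer counts; not all zero.
#' @return List with `accuracy`, `sensitivity`, `specificity`.
#' @examples
#' classification_metrics(tp = 8, tn = 7, fp = 3, fn = 2)
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stopf("confusion counts must be non-negative")
  total <- sum(counts)
  if (total == 0) stopf("all confusion counts are zero")
  list(accuracy = (tp + tn) / total,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Detection metrics from TP/FP/FN counts
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 TP / (2 TP + FP + FN)` (the harmonic mean of precision and
#' recall). Undefined metrics (zero denominator) are `NA`.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return List of class `detection_score` with `tp`, `fp`, `fn`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' detection_metrics(tp = 8, fp = 2, fn = 2)
#' @export
detection_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stopf("counts must be non-negative")
  if (tp + fp == 0 && tp + fn == 0)
    stopf("no predictions and no ground truth: metrics undefined")
  structure(list(
    tp = tp, fp = fp, fn = fn,
    precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_),
    class = "detection_score")
}

#' @export
print.detection_score <- function(x, ...) {
  cat(sprintf("detection score: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Match point annotations to predicted mask components
#'
#' Point-annotation detection scoring: each predicted component containing
#' at least one ground-truth point yields one true positive (matched to
#' the contained point nearest its centroid); surplus points inside an
#' already matched component count as false negatives (penalizing merged
#' detections); components containing no point are false positives; points
#' inside no component are false negatives.
#'
#' @param gt_points data frame or matrix of 0-based point coordinates:
#'   columns `(y, x)` for a 2-D mask or `(z, y, x)` for a 3-D one.
#' @param pred_components labeled mask: integer matrix or 3-D array
#'   (0 = background), e.g. from [label_components()].
#' @return List with `tp`, `fp`, `fn`.
#' @export
match_points_to_masks <- function(gt_points, pred_components) {
  comp <- unclass(pred_components)
  is3d <- length(dim(comp)) == 3L
  pts <- as.matrix(gt_points)
  n_pts <- nrow(pts)
  labs_at <- integer(n_pts)
  for (i in seq_len(n_pts)) {
    if (is3d) {
      z <- round(pts[i, 1]); y <- round(pts[i, 2]); x <- round(pts[i, 3])
      if (z < 0 || z >= dim(comp)[3] || y < 0 || y >= dim(comp)[1] ||
          x < 0 || x >= dim(comp)[2])
        stopf("ground-truth point %d lies outside the mask", i)
      labs_at[i] <- comp[y + 1, x + 1, z + 1]
    } else {
      y <- round(pts[i, 1]); x <- round(pts[i, 2])
      if (y < 0 || y >= nrow(comp) || x < 0 || x >= ncol(comp))
        stopf("ground-truth point %d lies outside the mask", i)
      labs_at[i] <- comp[y + 1, x + 1]
    }
  }
  all_labels <- setdiff(unique(as.integer(comp)), 0L)
  hit_labels <- setdiff(unique(labs_at), 0L)
  tp <- length(hit_labels)
  fp <- length(setdiff(all_labels, hit_labels))
  # points in background + surplus points in multiply-hit components
  fn <- sum(labs_at == 0L) + (sum(labs_at != 0L) - tp)
  list(tp = tp, fp = fp, fn = fn)
}

#' Match detected centers to ground-truth centers
#'
#' Greedy one-to-one matching by increasing distance: a detection within
#' `tol` of an unmatched ground-truth center is a true positive; leftover
#' detections are false positives and leftover centers false negatives.
#' Used to score the MPP detector against planted phantom particles.
#'
#' @param pred,gt data frames or matrices of center coordinates (same
#'   number of columns, any dimension).
#' @param tol matching tolerance (Euclidean distance).
#' @return A `detection_score`.
#' @export
match_centers <- function(pred, gt, tol) {
  pred <- as.matrix(pred); gt <- as.matrix(gt)
  np <- nrow(pred); ng <- nrow(gt)
  if (np == 0L || ng == 0L)
    return(detection_metrics(0L, np, ng))
  dm <- matrix(0, np, ng)
  for (j in seq_len(ng))
    dm[, j] <- sqrt(rowSums((pred - matrix(gt[j, ], np, ncol(gt),
                                           byrow = TRUE))^2))
  pairs <- which(dm <= tol, arr.ind = TRUE)
  if (nrow(pairs)) {
    pairs <- pairs[order(dm[pairs]), , drop = FALSE]
    used_p <- logical(np); used_g <- logical(ng); tp <- 0L
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!used_p[i] && !used_g[j]) {
        used_p[i] <- TRUE; used_g[j] <- TRUE; tp <- tp + 1L
      }
    }
  } else tp <- 0L
  detection_metrics(tp, np - tp, ng - tp)
}
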