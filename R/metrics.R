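# Confusion-matrix accumulation, segmentation metrics (mIoU, accuracy,
# precision/recall/F1, Cohen's kappa) and paired bootstrap model comparison.
# Convention: cm[i, j] counts pixels of reference class i predicted as class
# j (classes 0-indexed in masks, 1-indexed in the matrix).

#' Create an empty confusion matrix
#' @param nc number of classes (default 2).
#' @return `nc x nc` numeric matrix of zeros, class `wbs_confusion`.
#' @export
confusion_matrix <- function(nc = 2L) {
  structure(matrix(0, nc, nc,
                   dimnames = list(ref = paste0("c", seq_len(nc) - 1L),
                                   pred = paste0("c", seq_len(nc) - 1L))),
            class = c("wbs_confusion", "matrix", "array"))
}

#' Accumulate a prediction / reference pair into a confusion matrix
#'
#' Pure pixel counting; accumulation is order-independent, so a whole test set
#' can be pooled into one global matrix.
#'
#' @param pred,ref integer masks of identical shape, values in `0 .. nc - 1`.
#' @param cm a matrix from [confusion_matrix()] (or a prior accumulate).
#' @return the updated confusion matrix.
#' @export
cm_accumulate <- function(pred, ref, cm = confusion_matrix()) {
  if (!identical(dim(pred), dim(ref)) || length(pred) != length(ref)) {
    stop("pred and ref shapes disagree", call. = FALSE)
  }
  nc <- nrow(cm)
  pv <- as.integer(pred); rv <- as.integer(ref)
  if (max(pv, rv) >= nc || min(pv, rv) < 0L) {
    stop(sprintf("mask values must lie in 0..%d", nc - 1L), call. = FALSE)
  }
  counts <- tabulate(rv * nc + pv + 1L, nbins = nc * nc)
  cm + matrix(counts, nc, nc, byrow = TRUE, dimnames = dimnames(cm))
}

#' Build a binary confusion matrix from TP/FN/FP/TN counts
#'
#' Foreground is class 1: `cm[2, 2] = TP`, `cm[2, 1] = FN`, `cm[1, 2] = FP`,
#' `cm[1, 1] = TN`.
#'
#' @param tp,fn,fp,tn pixel counts.
#' @return a 2x2 `wbs_confusion` matrix.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn) {
  cm <- confusion_matrix(2L)
  cm[1, 1] <- tn; cm[1, 2] <- fp
  cm[2, 1] <- fn; cm[2, 2] <- tp
  cm
}

#' Per-class intersection over union
#' @param cm confusion matrix.
#' @return numeric vector of per-class IoU; `NA` for classes with zero union.
#' @export
per_class_iou <- function(cm) {
  nc <- nrow(cm)
  iou <- numeric(nc)
  for (i in seq_len(nc)) {
    union <- sum(cm[i, ]) + sum(cm[, i]) - cm[i, i]
    iou[i] <- if (union == 0) NA_real_ else cm[i, i] / union
  }
  iou
}

#' Mean intersection over union
#'
#' Average of per-class IoU over all classes. Classes with zero union (absent
#' from both masks) are excluded from the mean with a warning.
#'
#' @param cm confusion matrix.
#' @return scalar in `[0, 1]`.
#' @export
miou <- function(cm) {
  iou <- per_class_iou(cm)
  if (anyNA(iou)) {
    warning("classes with zero union excluded from mIoU: ",
            paste(which(is.na(iou)) - 1L, collapse = ", "), call. = FALSE)
  }
  mean(iou, na.rm = TRUE)
}

#' Overall pixel accuracy
#' @param cm confusion matrix.
#' @return scalar: trace / total.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  sum(diag(cm)) / total
}

#' Precision, recall and F1 of the foreground class
#'
#' Foreground is class 1 (second row/column). When a denominator is zero the
#' metric is reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param cm a 2x2 (or larger) confusion matrix.
#' @param foreground foreground class label (default 1).
#' @return list with `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(cm, foreground = 1L) {
  i <- foreground + 1L
  tp <- cm[i, i]
  fp <- sum(cm[, i]) - tp
  fn <- sum(cm[i, ]) - tp
  degen <- FALSE
  p <- if (tp + fp > 0) tp / (tp + fp) else { degen <- TRUE; 0 }
  r <- if (tp + fn > 0) tp / (tp + fn) else { degen <- TRUE; 0 }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else { degen <- TRUE; 0 }
  structure(list(precision = p, recall = r, f1 = f1), degenerate = degen)
}

#' F1 score (foreground by default, macro average optional)
#' @param cm confusion matrix.
#' @param average `"foreground"` (default) or `"macro"`.
#' @return scalar in `[0, 1]`.
#' @export
f1_score <- function(cm, average = c("foreground", "macro")) {
  average <- match.arg(average)
  if (average == "foreground") return(precision_recall_f1(cm)$f1)
  mean(vapply(seq_len(nrow(cm)) - 1L,
              function(k) precision_recall_f1(cm, k)$f1, numeric(1)))
}

#' Cohen's kappa
#'
#' `(po - pe) / (1 - pe)` with observed agreement `po = trace/total` and
#' chance agreement `pe = sum_i row_i * col_i / total^2`. The degenerate case
#' `pe = 1` is reported as 0 with attribute `degenerate = TRUE`.
#'
#' @param cm confusion matrix.
#' @return scalar.
#' @export
kappa <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (abs(1 - pe) < 1e-15) {
    return(structure(0, degenerate = TRUE))
  }
  (po - pe) / (1 - pe)
}

#' Full metrics report from a confusion matrix
#'
#' @param cm confusion matrix.
#' @return list with `miou`, `per_class_iou`, `accuracy`, `precision`,
#'   `recall`, `f1`, `kappa` and the raw `confusion` counts.
#' @export
metrics_report <- function(cm) {
  prf <- precision_recall_f1(cm)
  list(miou = miou(cm),
       per_class_iou = per_class_iou(cm),
       accuracy = accuracy(cm),
       precision = prf$precision,
       recall = prf$recall,
       f1 = prf$f1,
       kappa = as.numeric(kappa(cm)),
       confusion = unclass(cm))
}

#' Paired bootstrap comparison of two per-image score lists
#'
#' Resamples image indices with replacement (paired across the two models),
#' and returns 95% percentile intervals for each model's mean score and for
#' the paired difference `b - a`. The difference is called significant when
#' its interval excludes zero.
#'
#' @param scores_a,scores_b numeric vectors of per-image scores, equal length.
#' @param n_resamples number of bootstrap resamples (default 10000).
#' @param seed integer RNG seed.
#' @param conf confidence level (default 0.95).
#' @return A `wbs_bootstrap` list: `n_resamples`, `ci_a`, `ci_b`, `diff_ci`,
#'   `mean_diff`, `significant`, and the vector of resampled differences
#'   `diffs`.
#' @export
bootstrap_compare <- function(scores_a, scores_b, n_resamples = 10000L,
                              seed = 1L, conf = 0.95) {
  n <- length(scores_a)
  if (n == 0L || length(scores_b) != n) {
    stop("score lists must be non-empty and of equal length", call. = FALSE)
  }
  if (n_resamples < 1L) stop("n_resamples must be >= 1", call. = FALSE)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_resamples, replace = TRUE),
                nrow = n_resamples)
  ma <- rowMeans(matrix(scores_a[idx], nrow = n_resamples))
  mb <- rowMeans(matrix(scores_b[idx], nrow = n_resamples))
  alpha <- (1 - conf) / 2
  qs <- c(alpha, 1 - alpha)
  diff_ci <- unname(stats::quantile(mb - ma, qs))
  structure(list(n_resamples = as.integer(n_resamples),
                 ci_a = unname(stats::quantile(ma, qs)),
                 ci_b = unname(stats::quantile(mb, qs)),
                 diff_ci = diff_ci,
                 mean_diff = mean(mb - ma),
                 significant = diff_ci[1] > 0 || diff_ci[2] < 0,
                 diffs = mb - ma),
            class = "wbs_bootstrap")
}

#' @export
print.wbs_bootstrap <- function(x, ...) {
  cat(sprintf("Paired bootstrap (%d resamples)\n", x$n_resamples))
  cat(sprintf("  model A mean CI: [%.4f, %.4f]\n", x$ci_a[1], x$ci_a[2]))
  cat(sprintf("  model B mean CI: [%.4f, %.4f]\n", x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  difference (B - A): %.4f, CI [%.4f, %.4f] -> %s\n",
              x$mean_diff, x$diff_ci[1], x$diff_ci[2],
              if (x$significant) "significant" else "not significant"))
  invisible(x)
}
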