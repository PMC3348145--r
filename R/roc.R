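#' ROC curve, AUC and operating-point calibration for predictive scores
#'
#' Sweeps every threshold of the score vector under the rule
#' "score > threshold predicts the positive class", computes the ROC
#' curve and the trapezoid AUC, and chooses the score cutoff maximizing
#' Youden's J = sensitivity + specificity - 1 (ties resolved toward the
#' higher sensitivity). A user-supplied cutoff (for instance a
#' published operating point such as -0.16) overrides the calibration,
#' and its sensitivity/specificity are reported instead.
#'
#' @param scores numeric predictive scores.
#' @param labels character vector aligned to \code{scores}.
#' @param positive_class label treated as positive (default
#'   "sensitive").
#' @param cutoff optional fixed cutoff; NULL calibrates by Youden's J.
#' @return object of class \code{"wv_roc"}: list(points — data.frame
#'   (threshold, fpr, tpr), auc, cutoff, sensitivity, specificity,
#'   degenerate — TRUE when scores are constant, in which case AUC is
#'   0.5 and the cutoff undefined).
#' @export
roc_cutoff <- function(scores, labels, positive_class = "sensitive",
                       cutoff = NULL) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (diff(range(scores)) == 0) {
    return(structure(list(points = data.frame(threshold = c(Inf, -Inf),
                                              fpr = c(0, 1),
                                              tpr = c(0, 1)),
                          auc = 0.5, cutoff = NA_real_,
                          sensitivity = NA_real_,
                          specificity = NA_real_, degenerate = TRUE),
                     class = "wv_roc"))
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) mean(scores[pos] > t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] > t), 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  pts <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  if (is.null(cutoff)) {
    j <- tpr - fpr
    best <- which(j == max(j))
    best <- best[which.max(tpr[best])]
    cutoff <- thr[best]
    if (cutoff == Inf) cutoff <- max(scores)
    if (cutoff == -Inf) cutoff <- min(scores) - 1
  }
  structure(list(points = pts, auc = auc, cutoff = cutoff,
                 sensitivity = mean(scores[pos] > cutoff),
                 specificity = mean(scores[!pos] <= cutoff),
                 degenerate = FALSE),
            class = "wv_roc")
}

#' @export
print.wv_roc <- function(x, ...) {
  cat("ROC: AUC =", format(x$auc, digits = 4))
  if (x$degenerate) {
    cat(" (degenerate: constant scores, cutoff undefined)\n")
  } else {
    cat(", cutoff =", format(x$cutoff, digits = 4),
        sprintf("(sensitivity %.3f, specificity %.3f)\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' @export
plot.wv_roc <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  if (!x$degenerate)
    graphics::points(1 - x$specificity, x$sensitivity, pch = 19)
  invisible(x)
}

#' Overall accuracy implied by an operating point
#'
#' Bookkeeping identity linking sensitivity, specificity and class
#' sizes: accuracy = (sensitivity n_pos + specificity n_neg) /
#' (n_pos + n_neg). At the published training operating point
#' (sensitivity 0.952, specificity 0.70, 165 sensitive / 67 resistant)
#' this gives 0.879.
#'
#' @param sensitivity,specificity operating-point rates.
#' @param n_positive,n_negative class sizes.
#' @return overall accuracy as a fraction.
#' @export
operating_point_accuracy <- function(sensitivity, specificity,
                                     n_positive, n_negative) {
  stopifnot(n_positive > 0, n_negative > 0)
  (sensitivity * n_positive + specificity * n_negative) /
    (n_positive + n_negative)
}
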