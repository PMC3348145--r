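#' Fit a weighted-voting classifier
#'
#' The Golub-style weighted-voting model: each selected gene f casts a
#' vote \eqn{w_f (x_f - b_f)} for a new sample, where the weight
#' \eqn{w_f} is the gene's signal-to-noise ratio between the
#' chemosensitive and chemoresistant training samples and the boundary
#' \eqn{b_f} is the midpoint of its two class means. The predictive
#' score is the average vote \eqn{S = N^{-1} \sum_f w_f (x_f - b_f)};
#' samples scoring above the cutoff are called sensitive, at or below
#' it resistant.
#'
#' All weights, boundaries and class means are computed on the training
#' data only. Genes whose pooled spread is zero carry no usable vote
#' and are excluded with a warning.
#'
#' @param x genes x samples log2 expression matrix (training set).
#' @param labels named character vector, "sensitive"/"resistant",
#'   aligned to the columns of \code{x}.
#' @param entries optional data.frame of selected genes (from
#'   \code{\link{select_genes}} or \code{\link{select_morph_features}});
#'   by default all rows of \code{x} are used. Only the \code{feature}
#'   column is consulted — weights and boundaries are (re)computed here.
#' @param score_cutoff decision cutoff on the score scale; typically 0
#'   or an ROC-calibrated value (the published training cutoff was
#'   about -0.16). Stored in the model and used by
#'   \code{\link{predict.wv_model}}.
#' @param normalize logical; divide the vote sum by the number of genes
#'   (default). FALSE gives the unnormalized (ranking-equivalent) sum.
#' @return object of class \code{"wv_model"}: list(entries,
#'   score_cutoff, normalize, n_train, class_counts).
#' @export
#' @examples
#' sim <- simulate_expression(60, 200, 10, 2, 0.5, 0.3, seed = 3)
#' sel <- select_genes(sim$matrix, sim$labels, 1.5)
#' fit <- wv_fit(sim$matrix, sim$labels, sel)
#' table(predict(fit, sim$matrix, type = "class"), sim$labels)
wv_fit <- function(x, labels, entries = NULL, score_cutoff = 0,
                   normalize = TRUE) {
  labels <- check_labels(labels)
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  genes <- if (is.null(entries)) rownames(x) else entries$feature
  if (!length(genes)) stop("no genes to fit")
  missing <- setdiff(genes, rownames(x))
  if (length(missing))
    stop("genes absent from the matrix: ",
         paste(head(missing, 5), collapse = ", "))
  st <- row_class_stats(x[genes, , drop = FALSE], labels)
  bad <- is.na(st$w)
  if (any(bad)) {
    warning("excluding ", sum(bad), " degenerate gene(s) with zero spread")
    st <- st[!bad, , drop = FALSE]
  }
  if (!nrow(st)) stop("no usable genes after excluding degenerate ones")
  rownames(st) <- NULL
  structure(list(entries = st[, c("feature", "w", "mu_sensitive",
                                  "mu_resistant", "b")],
                 score_cutoff = score_cutoff, normalize = normalize,
                 n_train = length(labels),
                 class_counts = table(factor(labels,
                                             response_levels()))),
            class = "wv_model")
}

#' Predict weighted-voting scores or classes
#'
#' @param object a \code{"wv_model"}.
#' @param newdata genes x samples matrix, or a named numeric vector for
#'   one sample. Model genes missing from \code{newdata} are dropped
#'   from the vote with renormalization and a warning; no overlap is an
#'   error.
#' @param type "score" for the numeric predictive score, "class" for
#'   "sensitive"/"resistant" calls at \code{cutoff}.
#' @param cutoff score cutoff for class calls; defaults to the model's
#'   stored cutoff.
#' @param ... unused.
#' @return named numeric or character vector, one entry per sample.
#' @export
predict.wv_model <- function(object, newdata, type = c("score", "class"),
                             cutoff = object$score_cutoff, ...) {
  type <- match.arg(type)
  if (is.vector(newdata) && !is.list(newdata))
    newdata <- matrix(newdata, ncol = 1,
                      dimnames = list(names(newdata), "sample"))
  en <- object$entries
  present <- en$feature %in% rownames(newdata)
  if (!any(present)) stop("no model genes present in newdata")
  if (!all(present)) {
    warning(sum(!present), " model gene(s) missing from newdata; ",
            "vote renormalized over the ", sum(present), " present")
    en <- en[present, , drop = FALSE]
  }
  xm <- newdata[en$feature, , drop = FALSE]
  votes <- en$w * (xm - en$b)
  s <- colSums(votes)
  if (object$normalize) s <- s / nrow(en)
  if (type == "score") return(s)
  setNames(ifelse(s > cutoff, "sensitive", "resistant"), names(s))
}

#' @export
print.wv_model <- function(x, ...) {
  cat("Weighted-voting classifier\n")
  cat("  genes:", nrow(x$entries),
      " | training samples:", x$n_train,
      sprintf(" (%d sensitive / %d resistant)\n",
              x$class_counts[["sensitive"]],
              x$class_counts[["resistant"]]))
  cat("  score cutoff:", format(x$score_cutoff, digits = 4),
      if (x$normalize) "(mean vote)\n" else "(vote sum)\n")
  invisible(x)
}

#' @export
summary.wv_model <- function(object, ...) {
  en <- object$entries
  cat("Weighted-voting classifier —", nrow(en), "genes\n")
  cat("  weight (SNR) range: [",
      format(min(en$w), digits = 3), ", ",
      format(max(en$w), digits = 3), "]\n", sep = "")
  cat("  genes favoring sensitive (w > 0):", sum(en$w > 0),
      "| resistant:", sum(en$w < 0), "\n")
  invisible(structure(list(entries = en,
                           score_cutoff = object$score_cutoff),
                      class = "summary.wv_model"))
}

#' @export
coef.wv_model <- function(object, ...) {
  setNames(object$entries$w, object$entries$feature)
}

#' Leave-one-out accuracy of the full discovery-and-fit pipeline
#'
#' For each held-out sample, genes are re-selected and the
#' weighted-voting model re-fit on the remaining samples, then the
#' held-out sample is scored and called at score cutoff 0. This
#' measures the whole procedure, not a fixed gene list.
#'
#' @param x genes x samples log2 matrix.
#' @param labels named character vector aligned to columns.
#' @param fold_change_cutoff,p_max selection thresholds.
#' @return list(accuracy, calls, majority) — \code{majority} is the
#'   majority-class rate to compare against.
#' @export
wv_loo_accuracy <- function(x, labels, fold_change_cutoff = 1.5,
                            p_max = 0.05) {
  labels <- check_labels(labels)
  n <- length(labels)
  calls <- character(n)
  for (i in seq_len(n)) {
    sel <- select_genes(x[, -i, drop = FALSE], labels[-i],
                        fold_change_cutoff, p_max)
    if (!nrow(sel)) {
      calls[i] <- names(which.max(table(labels[-i])))
      next
    }
    fit <- wv_fit(x[, -i, drop = FALSE], labels[-i], sel)
    calls[i] <- predict(fit, x[, i], type = "class", cutoff = 0)
  }
  list(accuracy = mean(calls == labels), calls = calls,
       majority = max(table(labels)) / n)
}
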