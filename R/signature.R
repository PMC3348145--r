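#' Remove low-variation, low-expression genes
#'
#' Retains genes whose across-sample standard deviation exceeds the
#' given quantile of the SD distribution and whose median expression
#' exceeds the given quantile of the median distribution. Quantile 0
#' keeps everything.
#'
#' @param matrix genes x samples numeric matrix (log scale).
#' @param min_variation_quantile,min_median_quantile quantiles in
#'   \[0, 1\].
#' @return the retained submatrix.
#' @export
prescreen_genes <- function(matrix, min_variation_quantile = 0.25,
                            min_median_quantile = 0.25) {
  stopifnot(min_variation_quantile >= 0, min_variation_quantile <= 1,
            min_median_quantile >= 0, min_median_quantile <= 1)
  sds <- apply(matrix, 1, sd)
  meds <- apply(matrix, 1, median)
  keep <- (min_variation_quantile == 0 |
             sds > quantile(sds, min_variation_quantile)) &
          (min_median_quantile == 0 |
             meds > quantile(meds, min_median_quantile))
  if (!any(keep))
    stop("prescreen removed every gene; thresholds too aggressive")
  matrix[keep, , drop = FALSE]
}

#' Signal-to-noise ratio between two classes
#'
#' \eqn{(\mu_1 - \mu_2) / (\sigma_1 + \sigma_2)} with class 1 the
#' chemosensitive group; a positive value means higher expression in
#' the sensitive class. Standard deviations use the sample convention
#' (divisor n - 1).
#'
#' @param x values in class 1 (sensitive); at least 2 non-missing.
#' @param y values in class 2 (resistant); at least 2 non-missing.
#' @return the ratio, antisymmetric under class swap.
#' @export
snr <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("each class needs at least 2 non-missing values")
  s <- sd(x) + sd(y)
  if (s == 0) stop("degenerate feature: zero spread in both classes")
  (mean(x) - mean(y)) / s
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Classic FDR step-up: order the m p-values increasingly, compute
#' p_(i) m / i, and enforce monotonicity from the largest rank down;
#' values are capped at 1. Missing inputs propagate and do not count
#' toward m.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (!m) return(out)
  o <- order(p[ok])
  q <- p[ok][o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out[ok[o]] <- pmin(q, 1)
  out
}

# Vectorized per-row Welch two-sided t-test and class summaries.
# mat: features x samples; returns data.frame aligned to rownames(mat).
row_class_stats <- function(mat, labels) {
  labels <- check_labels(labels)
  is1 <- labels == "sensitive"
  stat1 <- function(m) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    v <- rowSums((m - mu)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mu = mu, v = v)
  }
  a <- stat1(mat[, is1, drop = FALSE])
  b <- stat1(mat[, !is1, drop = FALSE])
  se2 <- a$v / a$n + b$v / b$n
  tstat <- (a$mu - b$mu) / sqrt(se2)
  df <- se2^2 / ((a$v / a$n)^2 / pmax(a$n - 1, 1) +
                 (b$v / b$n)^2 / pmax(b$n - 1, 1))
  p <- 2 * pt(-abs(tstat), df)
  w <- (a$mu - b$mu) / (sqrt(a$v) + sqrt(b$v))
  bad <- a$n < 2 | b$n < 2 | (a$v + b$v) == 0
  p[bad] <- NA; w[bad] <- NA
  data.frame(feature = rownames(mat), mu_sensitive = a$mu,
             mu_resistant = b$mu, w = w,
             b = (a$mu + b$mu) / 2, t = tstat, p = p,
             stringsAsFactors = FALSE)
}

#' Select response-associated morphologic features
#'
#' Per-feature two-sided Welch t-test between chemosensitive and
#' chemoresistant samples with Benjamini-Hochberg adjustment; features
#' at q <= \code{fdr_max} are returned ranked by signal-to-noise ratio,
#' descending. A positive SNR marks a feature higher in the sensitive
#' class. Missing values (e.g. empty bins) are excluded pairwise per
#' feature; features with fewer than 2 usable values per class are
#' skipped.
#'
#' @param features samples x features matrix/data.frame (normalized).
#' @param labels named character vector aligned to the rows of
#'   \code{features}.
#' @param fdr_max FDR threshold (the published screen used 0.02).
#' @return data.frame (feature, w, mu_sensitive, mu_resistant, b, p, q)
#'   ordered by w descending; zero rows if nothing passes.
#' @export
select_morph_features <- function(features, labels, fdr_max = 0.02) {
  mat <- t(as.matrix(features))
  st <- row_class_stats(mat, labels)
  st$q <- bh_adjust(st$p)
  sel <- st[!is.na(st$q) & st$q <= fdr_max, , drop = FALSE]
  sel <- sel[order(-sel$w), c("feature", "w", "mu_sensitive",
                              "mu_resistant", "b", "p", "q")]
  rownames(sel) <- NULL
  sel
}

#' Select differentially expressed genes
#'
#' Keeps genes with |log2 fold change| at or above
#' log2(\code{fold_change_cutoff}) and two-sided Welch t-test p below
#' \code{p_max}. The fold change is the geometric-mean ratio
#' resistant / sensitive (2 to the class-mean difference, for log2
#' data). Each entry carries the weighted-voting ingredients: SNR
#' weight w and decision boundary b (midpoint of class means).
#'
#' @param matrix genes x samples log2 expression matrix (prescreened).
#' @param labels named character vector aligned to columns.
#' @param fold_change_cutoff ratio cutoff >= 1; 1 reduces to the pure
#'   t-test rule.
#' @param p_max p-value threshold.
#' @return data.frame (feature, w, mu_sensitive, mu_resistant, b,
#'   fold_change, p, q) — q is BH over all tested genes.
#' @export
select_genes <- function(matrix, labels, fold_change_cutoff = 1.5,
                         p_max = 0.05) {
  stopifnot(fold_change_cutoff >= 1)
  st <- row_class_stats(matrix, labels)
  st$q <- bh_adjust(st$p)
  lfc <- st$mu_resistant - st$mu_sensitive
  st$fold_change <- 2^lfc
  keep <- !is.na(st$p) & st$p < p_max &
    abs(lfc) >= log2(fold_change_cutoff)
  sel <- st[keep, c("feature", "w", "mu_sensitive", "mu_resistant",
                    "b", "fold_change", "p", "q")]
  rownames(sel) <- NULL
  sel
}

#' Tune the fold-change cutoff by training-set accuracy
#'
#' For each candidate cutoff: select genes, fit the weighted-voting
#' model, and score the training samples (resubstitution, score
#' cutoff 0). Returns the accuracy curve and the cutoff with the
#' highest accuracy (smallest cutoff on ties). A cutoff that selects no
#' genes contributes the majority-class rate and is flagged.
#'
#' @param matrix genes x samples log2 matrix.
#' @param labels named character vector aligned to columns.
#' @param candidate_cutoffs numeric vector of ratios >= 1.
#' @param p_max t-test threshold passed to \code{\link{select_genes}}.
#' @param method "resubstitution" (default) scores the training samples
#'   with the model fit on all of them; "loo" re-selects and re-fits
#'   per left-out sample (slower, resistant to overfitting).
#' @return list(best_cutoff, curve) where curve is a data.frame
#'   (cutoff, n_genes, accuracy, degenerate).
#' @export
tune_fold_change_cutoff <- function(matrix, labels, candidate_cutoffs,
                                    p_max = 0.05,
                                    method = c("resubstitution", "loo")) {
  stopifnot(length(candidate_cutoffs) >= 1)
  method <- match.arg(method)
  labels <- check_labels(labels)
  majority <- max(table(labels)) / length(labels)
  rows <- lapply(sort(candidate_cutoffs), function(ct) {
    sel <- select_genes(matrix, labels, ct, p_max)
    if (!nrow(sel))
      return(data.frame(cutoff = ct, n_genes = 0L, accuracy = majority,
                        degenerate = TRUE))
    acc <- if (method == "loo") {
      wv_loo_accuracy(matrix, labels, ct, p_max)$accuracy
    } else {
      fit <- wv_fit(matrix, labels, entries = sel)
      mean(predict(fit, matrix, type = "class", cutoff = 0) == labels)
    }
    data.frame(cutoff = ct, n_genes = nrow(sel), accuracy = acc,
               degenerate = FALSE)
  })
  curve <- do.call(rbind, rows)
  best <- curve$cutoff[which.max(curve$accuracy)]
  list(best_cutoff = best, curve = curve)
}

#' Split samples into high- and low-score groups at a quantile
#'
#' The round(\code{top_fraction} n) samples with the highest scores form
#' the "high" group, the rest the "low" group; ties are broken by
#' stable input order. With n = 244 and fraction 0.701 this yields the
#' published 171 / 73 split.
#'
#' @param scores numeric vector (names preserved).
#' @param top_fraction fraction in (0, 1).
#' @return character vector ("high"/"low"), same names/order as
#'   \code{scores}.
#' @export
split_by_quantile <- function(scores, top_fraction) {
  stopifnot(top_fraction > 0, top_fraction < 1)
  n <- length(scores)
  k <- as.integer(round(top_fraction * n))
  out <- rep("low", n)
  out[order(-scores)[seq_len(k)]] <- "high"
  names(out) <- names(scores)
  out
}

#' Jarque-Bera normality test
#'
#' JB = n/6 (g1^2 + (g2 - 3)^2 / 4) from the sample skewness g1 and
#' (non-excess) kurtosis g2, referred to a chi-square distribution with
#' 2 degrees of freedom.
#'
#' @param x numeric vector, n >= 8, not constant.
#' @return list(statistic, p_value).
#' @export
jarque_bera <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L) stop("jarque_bera needs at least 8 observations")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("constant vector: normality test undefined")
  g1 <- mean((x - m)^3) / m2^1.5
  g2 <- mean((x - m)^4) / m2^2
  stat <- n / 6 * (g1^2 + (g2 - 3)^2 / 4)
  list(statistic = stat, p_value = pchisq(stat, df = 2,
                                          lower.tail = FALSE))
}
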