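#' Supervised gene analysis on a feature-split cohort
#'
#' Two-sided Welch t-test of each gene between the "low" and "high"
#' groups of a morphologic median split, reporting genes below
#' \code{p_max} tagged by their direction in the low group (the
#' published screen found signature genes significantly lower, at
#' P < 0.01, in the low Std_Ar_Bin2 group).
#'
#' @param matrix genes x samples log2 expression matrix.
#' @param groups character vector ("high"/"low") aligned to columns;
#'   NA samples are dropped.
#' @param p_max p-value threshold.
#' @param genes optional gene subset (e.g. the discovered signature).
#' @return data.frame (gene, mean_low, mean_high, p, direction) with
#'   direction "lower"/"higher" in the low group, ordered by p.
#' @export
supervised_gene_analysis <- function(matrix, groups, p_max = 0.01,
                                     genes = NULL) {
  stopifnot(ncol(matrix) == length(groups))
  ok <- !is.na(groups)
  matrix <- matrix[, ok, drop = FALSE]
  groups <- groups[ok]
  if (!all(groups %in% c("high", "low")))
    stop("groups must be 'high'/'low'")
  if (min(table(groups)) < 2L) stop("each group needs >= 2 samples")
  if (!is.null(genes)) matrix <- matrix[intersect(genes,
                                                  rownames(matrix)), ,
                                        drop = FALSE]
  lab <- ifelse(groups == "low", "sensitive", "resistant")  # reuse
  st <- row_class_stats(matrix, lab)
  st <- st[!is.na(st$p) & st$p < p_max, , drop = FALSE]
  out <- data.frame(gene = st$feature, mean_low = st$mu_sensitive,
                    mean_high = st$mu_resistant, p = st$p,
                    direction = ifelse(st$mu_sensitive < st$mu_resistant,
                                       "lower", "higher"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}

#' Feature-gene correlation mapping
#'
#' Pearson correlation of every (morphologic feature, gene) pair over
#' the samples shared by the two matrices, with pairwise deletion of
#' missing values. Pairs with p below \code{p_max} are returned with
#' the correlation sign ("positive"/"negative"); no multiplicity
#' correction is applied at this screen, matching the published
#' P < 0.005 threshold. Zero-variance vectors are skipped with a
#' warning. Spearman correlation is available via \code{method}.
#'
#' @param features samples x features matrix/data.frame (normalized).
#' @param matrix genes x samples expression matrix.
#' @param p_max p-value threshold.
#' @param method "pearson" (default) or "spearman".
#' @return data.frame (feature, gene, r, p, sign) ordered by p.
#' @export
feature_gene_correlation <- function(features, matrix, p_max = 0.005,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  shared <- intersect(rownames(features), colnames(matrix))
  if (length(shared) < 5L) stop("need >= 5 shared samples")
  fm <- as.matrix(features)[shared, , drop = FALSE]
  gm <- t(matrix[, shared, drop = FALSE])
  if (method == "spearman") {
    fm <- apply(fm, 2, rank, na.last = "keep")
    gm <- apply(gm, 2, rank, na.last = "keep")
  }
  const <- function(m) apply(m, 2, function(v)
    length(unique(v[!is.na(v)])) < 2L)
  cf <- const(fm); cg <- const(gm)
  if (any(cf) || any(cg))
    warning("skipping ", sum(cf), " zero-variance feature(s) and ",
            sum(cg), " zero-variance gene(s)")
  fm <- fm[, !cf, drop = FALSE]; gm <- gm[, !cg, drop = FALSE]
  r <- stats::cor(fm, gm, use = "pairwise.complete.obs")
  n <- crossprod(!is.na(fm), !is.na(gm))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), pmax(n - 2, 1))
  p[n < 3] <- NA
  hit <- which(!is.na(p) & p < p_max, arr.ind = TRUE)
  out <- data.frame(feature = colnames(fm)[hit[, 1]],
                    gene = colnames(gm)[hit[, 2]],
                    r = r[hit], p = p[hit],
                    sign = ifelse(r[hit] >= 0, "positive", "negative"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), ]
  rownames(out) <- NULL
  out
}
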