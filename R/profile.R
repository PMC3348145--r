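#' Assign a nuclear area to one of the evenly spaced size bins
#'
#' Ten bins of width 45 px^2 span the retained size range 50-500 px^2.
#' Bin b covers \[50 + (b-1) 45, 50 + b 45) — half-open, except the last
#' bin, which is closed at 500 so every in-range area has a bin.
#'
#' @param area nuclear area(s), px^2, already inside
#'   \[area_min, area_max\].
#' @param area_min,area_max size-range bounds, px^2.
#' @param n_bins number of bins.
#' @return integer bin index in 1..n_bins (vectorized).
#' @export
#' @examples
#' assign_bin(c(50, 94.999, 95, 500))  # 1 1 2 10
assign_bin <- function(area, area_min = 50, area_max = 500, n_bins = 10L) {
  if (any(area < area_min | area > area_max))
    stop("area outside [", area_min, ", ", area_max,
         "]: run filter_nuclei first")
  w <- (area_max - area_min) / n_bins
  b <- pmin(as.integer(floor((area - area_min) / w)) + 1L, n_bins)
  b
}

# Parameter codes and the measurement columns they summarize.
profile_params <- function() {
  c(Ar = "area", Pe = "perimeter", Ci = "circularity",
    AR = "aspect_ratio", So = "solidity", Ro = "roundness")
}

#' Canonical names of the 153 profile features
#'
#' Order: Mean_P_b for the six parameters (Ar, Pe, Ci, AR, So, Ro)
#' across Bin1..Bin10 and Total (66), then Std_P_b likewise (66), then
#' Count_Bin1..10, Pct_Bin1..10, and Compactness.
#'
#' @param n_bins number of size bins.
#' @return character vector of length 153 (for the default 10 bins).
#' @export
profile_feature_names <- function(n_bins = 10L) {
  bins <- c(paste0("Bin", seq_len(n_bins)), "Total")
  p <- names(profile_params())
  c(paste0("Mean_", rep(p, each = length(bins)), "_", bins),
    paste0("Std_",  rep(p, each = length(bins)), "_", bins),
    paste0("Count_Bin", seq_len(n_bins)),
    paste0("Pct_Bin", seq_len(n_bins)),
    "Compactness")
}

#' Build the 153-feature nuclear image profile of one sample
#'
#' Summarizes a sample's retained nuclei (pooled over its images) as the
#' size-binned tumor nuclear image profile: per-bin and overall means
#' and standard deviations of area, perimeter, circularity, aspect
#' ratio, solidity and roundness (2 x 6 x 11 = 132 features), the
#' per-bin nucleus counts and percentages (20), and one spatial
#' compactness value (Clark-Evans index, \code{\link{compactness}}) —
#' 153 features in all.
#'
#' Standard deviations use the population convention (divisor n), so a
#' single-nucleus bin has SD 0 rather than a missing value. Empty bins
#' yield missing means/SDs (a zero would fabricate a shape value) and
#' zero counts; percentages are missing when the sample has no nuclei.
#'
#' @param measurements data.frame of retained nuclei (columns area,
#'   perimeter, circularity, aspect_ratio, solidity, roundness, x, y,
#'   and optionally image_id for multi-image samples).
#' @param sample_id sample identifier.
#' @param image_shape (height, width) of the source images, px; needed
#'   for compactness.
#' @param area_min,area_max,n_bins binning parameters.
#' @return named numeric vector of length 153 with class
#'   \code{"morph_profile"}; attribute \code{sample_id}.
#' @export
build_profile <- function(measurements, sample_id = "sample",
                          image_shape = c(648L, 1072L),
                          area_min = 50, area_max = 500, n_bins = 10L) {
  nm <- profile_feature_names(n_bins)
  params <- profile_params()
  n <- nrow(measurements)
  prof <- setNames(rep(NA_real_, length(nm)), nm)
  bins <- if (n) assign_bin(measurements$area, area_min, area_max, n_bins)
          else integer(0)
  counts <- tabulate(bins, nbins = n_bins)
  pop_sd <- function(v) if (!length(v)) NA_real_
           else sqrt(mean((v - mean(v))^2))
  for (code in names(params)) {
    v <- measurements[[params[[code]]]]
    for (b in seq_len(n_bins)) {
      vb <- v[bins == b]
      prof[paste0("Mean_", code, "_Bin", b)] <-
        if (length(vb)) mean(vb) else NA_real_
      prof[paste0("Std_", code, "_Bin", b)] <- pop_sd(vb)
    }
    prof[paste0("Mean_", code, "_Total")] <- if (n) mean(v) else NA_real_
    prof[paste0("Std_", code, "_Total")] <- pop_sd(v)
  }
  prof[paste0("Count_Bin", seq_len(n_bins))] <- counts
  prof[paste0("Pct_Bin", seq_len(n_bins))] <-
    if (n) 100 * counts / n else NA_real_
  prof["Compactness"] <- if (n >= 2)
    compactness(measurements$x, measurements$y, image_shape,
                image_id = measurements$image_id) else NA_real_
  stopifnot(length(prof) == 153L || n_bins != 10L)
  structure(prof, sample_id = sample_id, class = "morph_profile")
}

#' @export
print.morph_profile <- function(x, ...) {
  cat("Nuclear image profile of sample '", attr(x, "sample_id"),
      "' (", length(x), " features)\n", sep = "")
  cat("  nuclei:", sum(x[grep("^Count_", names(x))]), "\n")
  cat("  Mean_Ar_Total:", format(x[["Mean_Ar_Total"]], digits = 4),
      " Compactness:", format(x[["Compactness"]], digits = 4), "\n")
  invisible(x)
}

#' Spatial compactness of nuclei (Clark-Evans index)
#'
#' Ratio of the observed mean nearest-neighbour distance between nucleus
#' centroids to its expectation under complete spatial randomness,
#' \eqn{0.5\sqrt{A/n}} for n points in an image of area A. Values below
#' 1 indicate clustering, near 1 spatial randomness, above 1 regularity.
#' With several images per sample the index is computed per image and
#' combined as a nucleus-count-weighted mean.
#'
#' @param x,y centroid coordinates, px.
#' @param image_shape (height, width) of one image, px.
#' @param image_id optional per-nucleus image identifier.
#' @return the index, or NA for fewer than 2 points.
#' @export
compactness <- function(x, y, image_shape, image_id = NULL) {
  if (is.null(image_id)) image_id <- rep(1L, length(x))
  stopifnot(length(x) == length(y), length(image_id) == length(x))
  area <- prod(image_shape[1:2])
  per_image <- function(i) {
    xi <- x[image_id == i]; yi <- y[image_id == i]
    n <- length(xi)
    if (n < 2L) return(c(NA_real_, n))
    d <- as.matrix(dist(cbind(xi, yi)))
    diag(d) <- Inf
    mean_nn <- mean(apply(d, 1, min))
    c(mean_nn / (0.5 * sqrt(area / n)), n)
  }
  res <- vapply(unique(image_id), per_image, numeric(2))
  ok <- !is.na(res[1, ])
  if (!any(ok)) return(NA_real_)
  sum(res[1, ok] * res[2, ok]) / sum(res[2, ok])
}

#' Stack per-sample profiles into a feature matrix
#'
#' @param profiles list of \code{\link{build_profile}} results.
#' @return data.frame, rows = samples (rownames = sample ids),
#'   columns = 153 features; attribute \code{provenance = "raw"}.
#' @export
profile_matrix <- function(profiles) {
  stopifnot(length(profiles) > 0)
  m <- do.call(rbind, lapply(profiles, unclass))
  rownames(m) <- vapply(profiles, attr, "", "sample_id")
  structure(as.data.frame(m), provenance = "raw")
}

#' Normalize a profile matrix for cross-sample analysis
#'
#' Each feature column is log-transformed and centred on its median:
#' x -> log(x / median(x)), giving every feature median 0. Raw values
#' that are not strictly positive cannot be log-scaled; they become
#' missing and are excluded from the feature's median (a warning
#' reports how many). Missing inputs propagate.
#'
#' @param features data.frame or matrix, samples x features, raw scale.
#' @return data.frame of the same shape, \code{provenance =
#'   "normalized"}.
#' @export
normalize_profiles <- function(features) {
  m <- as.matrix(features)
  n_bad <- sum(m <= 0, na.rm = TRUE)
  if (n_bad)
    warning(n_bad, " non-positive value(s) set to missing before log")
  m[m <= 0] <- NA
  lm <- log(m)
  med <- apply(lm, 2, median, na.rm = TRUE)
  out <- sweep(lm, 2, med, "-")
  structure(as.data.frame(out), provenance = "normalized")
}
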