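#' FFT band-pass filter for nucleus enhancement
#'
#' Removes image structure smaller than \code{band_low} pixels (noise)
#' and larger than \code{band_high} pixels (illumination and tissue
#' background) with Gaussian low- and high-pass transfer functions in
#' the Fourier domain, each at half power at its cutoff. The image is
#' mirror-padded before the transform to avoid wrap-around edge
#' artifacts. Nuclei of 50-500 px^2 (diameters roughly 8-25 px) pass the
#' default 3-40 px band essentially untouched.
#'
#' @param image 2-D numeric matrix.
#' @param band_low smallest structure size kept, pixels.
#' @param band_high largest structure size kept, pixels.
#' @return matrix of the same dimensions, zero-mean band-passed signal.
#' @export
fft_bandpass <- function(image, band_low = 3, band_high = 40) {
  stopifnot(is.matrix(image), band_low < band_high, band_low > 0)
  h <- nrow(image); w <- ncol(image)
  pad <- rbind(cbind(image, image[, w:1]),
               cbind(image[h:1, ], image[h:1, w:1]))
  H <- nrow(pad); W <- ncol(pad)
  fy <- pmin(0:(H - 1), H - (0:(H - 1))) / H   # cycles per pixel
  fx <- pmin(0:(W - 1), W - (0:(W - 1))) / W
  r2 <- outer(fy^2, fx^2, "+")
  f_hi <- 1 / band_low
  f_lo <- 1 / band_high
  gain <- exp(-log(2) * r2 / f_hi^2) * (1 - exp(-log(2) * r2 / f_lo^2))
  filt <- Re(fft(fft(pad) * gain, inverse = TRUE)) / (H * W)
  filt[seq_len(h), seq_len(w)]
}

#' Convert an intensity image to a binary nucleus mask
#'
#' Band-pass filters the image and thresholds it. Nuclei are assumed
#' darker than the background (the hematoxylin convention), so
#' foreground is where the filtered signal falls below the threshold.
#' With \code{threshold = "auto"} the threshold is Otsu's method on the
#' filtered image — a deterministic stand-in for manual threshold
#' verification against the original slide; a numeric value overrides
#' it (applied on the filtered, zero-mean scale).
#'
#' @param image 2-D numeric matrix, or 3-D array (RGB), converted to
#'   grayscale by luminance (0.299 R + 0.587 G + 0.114 B) or by taking
#'   the channel named in \code{channel}.
#' @param band_low,band_high band-pass structure-size cutoffs, pixels.
#' @param threshold "auto" for Otsu, or a numeric cutoff on the
#'   band-passed intensity scale.
#' @param dark_foreground logical; TRUE (default) marks pixels below the
#'   threshold as foreground.
#' @param channel NULL for luminance, or 1/2/3 to take a single channel
#'   of an RGB array.
#' @return logical matrix, TRUE = nucleus foreground.
#' @export
preprocess_to_mask <- function(image, band_low = 3, band_high = 40,
                               threshold = "auto", dark_foreground = TRUE,
                               channel = NULL) {
  image <- as_grayscale(image, channel)
  if (diff(range(image)) == 0 && identical(threshold, "auto"))
    stop("degenerate input: constant image has no automatic threshold")
  filt <- fft_bandpass(image, band_low, band_high)
  if (identical(threshold, "auto")) {
    rng <- range(filt)
    if (diff(rng) == 0)
      stop("degenerate input: band-passed image is constant")
    scaled <- (filt - rng[1]) / diff(rng)
    t01 <- EBImage::otsu(EBImage::Image(t(scaled)), range = c(0, 1))
    thr <- rng[1] + t01 * diff(rng)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    thr <- threshold
  }
  if (dark_foreground) filt < thr else filt > thr
}

as_grayscale <- function(image, channel = NULL) {
  if (is.matrix(image)) return(image)
  if (length(dim(image)) == 3L) {
    if (!is.null(channel)) return(image[, , channel])
    if (dim(image)[3] >= 3L)
      return(0.299 * image[, , 1] + 0.587 * image[, , 2] +
             0.114 * image[, , 3])
    return(image[, , 1])
  }
  stop("image must be a 2-D matrix or 3-D array")
}

#' Label connected foreground components
#'
#' Labels 8-connected components of a binary mask (two foreground pixels
#' belong to the same nucleus if they touch edge- or corner-wise).
#' Component membership is computed on the 8-neighbour pixel graph;
#' labels are assigned in raster order of each component's first pixel.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same dimensions; 0 = background,
#'   1..k = component labels.
#' @export
segment_mask <- function(mask) {
  stopifnot(is.matrix(mask))
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask)
  lab <- matrix(0L, h, w)
  if (!length(idx)) return(lab)
  id <- matrix(0L, h, w)
  id[idx] <- seq_along(idx)
  edges <- list()
  shifts <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  for (s in shifts) {
    r2 <- r + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    keep <- nb > 0L
    if (any(keep))
      edges[[length(edges) + 1L]] <-
        cbind(id[idx[ok]][keep], nb[keep])
  }
  if (length(edges)) {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) -
                                       igraph::vcount(g)))
    memb <- igraph::components(g)$membership[seq_along(idx)]
  } else {
    memb <- seq_along(idx)
  }
  # relabel so components are numbered by first appearance in raster
  # order (column-major, matching which())
  first <- !duplicated(memb)
  relab <- integer(max(memb))
  relab[memb[first]] <- seq_len(sum(first))
  lab[idx] <- relab[memb]
  lab
}

#' Shape descriptors from primary measurements
#'
#' Computes the four dimensionless descriptors used in the nuclear
#' profile: circularity \eqn{4\pi A / P^2} (capped at 1; pixelation can
#' push the raw value above 1), aspect ratio major/minor, roundness
#' \eqn{4A/(\pi\,\mathrm{major}^2)} (capped at 1) and solidity
#' A / convex area (capped at 1).
#'
#' @param area region area, px^2.
#' @param perimeter boundary length, px.
#' @param major_axis,minor_axis full lengths of the fitted-ellipse axes,
#'   px.
#' @param convex_area convex hull area, px^2.
#' @return named numeric vector (circularity, aspect_ratio, roundness,
#'   solidity).
#' @export
shape_descriptors <- function(area, perimeter, major_axis, minor_axis,
                              convex_area) {
  if (any(!is.finite(c(area, perimeter, major_axis, minor_axis,
                       convex_area))) ||
      perimeter <= 0 || major_axis <= 0 || minor_axis <= 0 ||
      area <= 0 || convex_area <= 0)
    stop("invalid measurement: all inputs must be positive and finite")
  if (major_axis < minor_axis)
    stop("major_axis must be >= minor_axis")
  c(circularity = min(1, 4 * pi * area / perimeter^2),
    aspect_ratio = major_axis / minor_axis,
    roundness = min(1, 4 * area / (pi * major_axis^2)),
    solidity = min(1, area / convex_area))
}

#' Measure every labeled region of a segmented image
#'
#' For each region: area = pixel count; perimeter = isothetic
#' crack-boundary length scaled by pi/4 (unbiased for digitized disks);
#' centroid of pixel centres (0-based, x = column); ellipse axes from
#' second-order central moments with the +1/12 per-pixel variance
#' correction; convex area from the hull of pixel corners; descriptors
#' via \code{\link{shape_descriptors}}. Single-pixel regions are
#' degenerate and dropped with a warning.
#'
#' @param labels integer label matrix from \code{\link{segment_mask}}.
#' @return data.frame with one row per region: label, area, perimeter,
#'   x, y, major_axis, minor_axis, convex_area, circularity,
#'   aspect_ratio, roundness, solidity.
#' @export
measure_regions <- function(labels) {
  stopifnot(is.matrix(labels))
  k <- max(labels)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), x = numeric(0),
                      y = numeric(0), major_axis = numeric(0),
                      minor_axis = numeric(0), convex_area = numeric(0),
                      circularity = numeric(0), aspect_ratio = numeric(0),
                      roundness = numeric(0), solidity = numeric(0))
  if (k == 0L) return(empty)
  h <- nrow(labels); w <- ncol(labels)
  idx <- which(labels > 0L)
  lb <- labels[idx]
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  # crack count: 4-neighbour transitions out of the same label
  crack <- integer(k)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- labels
  for (s in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L))) {
    nb <- pad[cbind(r + 1L + s[1], cc + 1L + s[2])]
    diff_lab <- nb != lb
    tab <- tabulate(lb[diff_lab], nbins = k)
    crack <- crack + tab
  }
  rows <- split(seq_along(idx), lb)
  out <- lapply(seq_len(k), function(j) {
    i <- rows[[as.character(j)]]
    measure_pixels(cc[i] - 1, r[i] - 1, crack[j], j)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) empty else res
}

# x, y are 0-based pixel-centre coordinates of one region.
measure_pixels <- function(x, y, crack, label) {
  n <- length(x)
  if (n < 2L) {
    warning("dropping single-pixel region (degenerate moments)")
    return(NULL)
  }
  perim <- crack * pi / 4
  mx <- mean(x); my <- mean(y)
  # central moments + 1/12 pixel-extent correction
  cxx <- mean((x - mx)^2) + 1 / 12
  cyy <- mean((y - my)^2) + 1 / 12
  cxy <- mean((x - mx) * (y - my))
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  conv <- convex_area_pixels(x, y)
  d <- shape_descriptors(n, perim, major, minor, conv)
  data.frame(label = label, area = as.numeric(n), perimeter = perim,
             x = mx, y = my, major_axis = major, minor_axis = minor,
             convex_area = conv,
             circularity = d[["circularity"]],
             aspect_ratio = d[["aspect_ratio"]],
             roundness = d[["roundness"]],
             solidity = d[["solidity"]])
}

# Area of the convex hull of the region treated as a union of unit
# pixel squares: hull over the four corners of every pixel, shoelace.
convex_area_pixels <- function(x, y) {
  px <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  py <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  hp <- chull(px, py)
  hx <- px[hp]; hy <- py[hp]
  j <- c(seq_along(hp)[-1], 1L)
  abs(sum(hx * hy[j] - hx[j] * hy)) / 2
}

#' Retain nuclei by size and circularity
#'
#' Keeps measurements with \code{area_min <= area <= area_max}
#' (inclusive bounds) and \code{circularity > circularity_min} (strict),
#' preserving order — the published gate of 50-500 px^2 and circularity
#' greater than 0.3.
#'
#' @param measurements data.frame from \code{\link{measure_regions}}.
#' @param area_min,area_max inclusive area bounds, px^2.
#' @param circularity_min strict lower circularity bound.
#' @return the retained subset, same columns and order.
#' @export
filter_nuclei <- function(measurements, area_min = 50, area_max = 500,
                          circularity_min = 0.3) {
  stopifnot(area_min <= area_max)
  keep <- measurements$area >= area_min & measurements$area <= area_max &
    measurements$circularity > circularity_min
  measurements[keep, , drop = FALSE]
}

#' Segment and measure nuclei from an intensity image
#'
#' The full per-image chain: band-pass and threshold
#' (\code{\link{preprocess_to_mask}}), 8-connected labeling
#' (\code{\link{segment_mask}}), per-region measurement
#' (\code{\link{measure_regions}}) and the size/circularity gate
#' (\code{\link{filter_nuclei}}).
#'
#' @param image intensity matrix (or RGB array).
#' @param band_low,band_high,threshold,dark_foreground,channel passed to
#'   \code{\link{preprocess_to_mask}}.
#' @param area_min,area_max,circularity_min passed to
#'   \code{\link{filter_nuclei}}.
#' @return data.frame of retained nucleus measurements.
#' @export
extract_nuclei <- function(image, band_low = 3, band_high = 40,
                           threshold = "auto", dark_foreground = TRUE,
                           channel = NULL, area_min = 50, area_max = 500,
                           circularity_min = 0.3) {
  mask <- preprocess_to_mask(image, band_low, band_high, threshold,
                             dark_foreground, channel)
  m <- measure_regions(segment_mask(mask))
  filter_nuclei(m, area_min, area_max, circularity_min)
}
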