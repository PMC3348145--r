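#' Simulate a microscopy-style image of elliptical nuclei
#'
#' Renders dark, anti-aliased filled ellipses ("nuclei") on a lighter
#' background with additive Gaussian noise, together with a ground-truth
#' table recording every ellipse. The geometry emulates 20x
#' hematoxylin-and-eosin fields in which nuclei occupy roughly 50-500
#' square pixels; defaults match that regime (648 x 1072 px fields with
#' on the order of 400 nuclei each).
#'
#' Nuclei are placed by rejection sampling so that no two ellipses
#' overlap (conservative test: centre distance greater than the sum of
#' semi-major axes plus a 2 px guard). Centres keep a margin from the
#' image border so every nucleus is fully contained.
#'
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param image_shape integer (height, width) in pixels.
#' @param area_range interval of ellipse areas in px^2 (uniformly sampled).
#' @param elongation_range interval of major/minor axis ratios (>= 1).
#' @param background_noise_sd standard deviation of additive Gaussian
#'   noise on the 0-1 intensity scale.
#' @param foreground,background mean intensities of nuclei and background.
#' @param seed integer seed; identical arguments and seed reproduce the
#'   image bit for bit.
#' @param max_attempts rejection-sampling budget; exceeding it signals an
#'   over-dense request.
#'
#' @return list with elements \code{image} (height x width matrix of
#'   intensities in \[0, 1\]) and \code{truth}, a data.frame with one row
#'   per nucleus: \code{x}, \code{y} (centre, 0-based pixel coordinates,
#'   x = column), \code{a}, \code{b} (semi-major/minor axes, px),
#'   \code{theta} (orientation, radians) and \code{area} (analytic
#'   ellipse area pi*a*b). Attributes record \code{image_shape} and
#'   \code{seed}.
#' @export
#' @examples
#' im <- simulate_nuclei_image(12, image_shape = c(128, 128),
#'                             area_range = c(80, 300), seed = 1)
#' nrow(im$truth)
simulate_nuclei_image <- function(n_nuclei,
                                  image_shape = c(648L, 1072L),
                                  area_range = c(50, 500),
                                  elongation_range = c(1, 2.5),
                                  background_noise_sd = 0.02,
                                  foreground = 0.25,
                                  background = 0.85,
                                  seed = 1L,
                                  max_attempts = 10000L) {
  stopifnot(n_nuclei >= 0, length(image_shape) == 2L,
            area_range[1] > 0, area_range[1] <= area_range[2],
            elongation_range[1] >= 1,
            elongation_range[1] <= elongation_range[2],
            background_noise_sd >= 0)
  h <- as.integer(image_shape[1]); w <- as.integer(image_shape[2])
  if (area_range[2] >= h * w) stop("area_range exceeds the image area")

  with_seed(seed, {
    placed <- data.frame(x = numeric(0), y = numeric(0), a = numeric(0),
                         b = numeric(0), theta = numeric(0))
    attempts <- 0L
    while (nrow(placed) < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("could not place ", n_nuclei, " non-overlapping nuclei in ",
             max_attempts, " attempts; request is over-dense")
      area  <- runif(1, area_range[1], area_range[2])
      elong <- runif(1, elongation_range[1], elongation_range[2])
      a <- sqrt(area * elong / pi)
      b <- sqrt(area / (pi * elong))
      margin <- a + 2
      if (2 * margin >= min(h, w))
        stop("nucleus too large for the image")
      x <- runif(1, margin, w - 1 - margin)
      y <- runif(1, margin, h - 1 - margin)
      if (nrow(placed)) {
        d <- sqrt((placed$x - x)^2 + (placed$y - y)^2)
        if (any(d < placed$a + a + 2)) next
      }
      placed <- rbind(placed, data.frame(x = x, y = y, a = a, b = b,
                                         theta = runif(1, 0, pi)))
    }

    img <- matrix(background, nrow = h, ncol = w)
    if (nrow(placed)) {
      for (i in seq_len(nrow(placed)))
        img <- draw_ellipse(img, placed[i, ], foreground, background)
    }
    img <- img + matrix(rnorm(h * w, 0, background_noise_sd), h, w)
    img[img < 0] <- 0; img[img > 1] <- 1

    truth <- placed
    truth$area <- pi * truth$a * truth$b
    attr(truth, "image_shape") <- c(h, w)
    attr(truth, "seed") <- as.integer(seed)
    list(image = img, truth = truth)
  })
}

# Blend one anti-aliased filled ellipse into `img` using 4x4 subpixel
# coverage within the ellipse bounding box. Pixel centres are 0-based.
draw_ellipse <- function(img, e, foreground, background) {
  h <- nrow(img); w <- ncol(img)
  rmax <- e$a + 1
  cols <- max(1L, floor(e$x - rmax) + 1L):min(w, ceiling(e$x + rmax) + 1L)
  rows <- max(1L, floor(e$y - rmax) + 1L):min(h, ceiling(e$y + rmax) + 1L)
  off <- (seq_len(4) - 2.5) / 4
  cth <- cos(e$theta); sth <- sin(e$theta)
  cov <- matrix(0, length(rows), length(cols))
  px <- (cols - 1)   # 0-based x of pixel centres
  py <- (rows - 1)
  for (oy in off) for (ox in off) {
    dx <- outer(rep(1, length(rows)), px + ox - e$x)
    dy <- outer(py + oy - e$y, rep(1, length(cols)))
    u <- (dx * cth + dy * sth) / e$a
    v <- (-dx * sth + dy * cth) / e$b
    cov <- cov + (u * u + v * v <= 1)
  }
  cov <- cov / 16
  img[rows, cols] <- img[rows, cols] * (1 - cov) + foreground * cov
  img
}
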