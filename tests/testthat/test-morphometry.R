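test_that("band-pass passes in-band sinusoids and rejects out-of-band ones", {
  n <- 128
  # cosine waves of period 2n/k are even under the mirror extension the
  # filter uses, so each probe is a pure frequency
  wave <- function(k) outer(rep(1, n), cos(pi * k * (0:(n - 1)) / n))
  for (case in list(list(k = 32, lo = 0.5, hi = Inf),   # period 8 px
                    list(k = 2, lo = 0, hi = 0.1),      # period 128 px
                    list(k = 128, lo = 0, hi = 0.1))) { # period 2 px
    img <- wave(case$k)
    out <- fft_bandpass(img, band_low = 3, band_high = 40)
    ratio <- var(as.vector(out)) / var(as.vector(img))
    expect_gte(ratio, case$lo)
    expect_lte(ratio, case$hi)
  }
})

test_that("constant images are degenerate for automatic thresholding", {
  img <- matrix(0.5, 64, 64)
  out <- fft_bandpass(img)
  expect_lt(diff(range(out)), 1e-8)
  expect_error(preprocess_to_mask(img), "degenerate")
})

test_that("mask foreground area tracks the analytic disk areas", {
  sim <- simulate_nuclei_image(25, c(300, 300), area_range = c(150, 350),
                               elongation_range = c(1, 1),
                               background_noise_sd = 0.01, seed = 31)
  mask <- preprocess_to_mask(sim$image)
  expect_equal(dim(mask), dim(sim$image))
  expect_equal(sum(mask), sum(sim$truth$area), tolerance = 0.15)
})

test_that("segmentation labels 8-connected components", {
  expect_equal(max(segment_mask(matrix(FALSE, 10, 10))), 0)

  m <- matrix(FALSE, 20, 20)
  m[2:5, 2:5] <- TRUE      # 16 px square
  m[10:15, 12:17] <- TRUE  # 36 px square
  lab <- segment_mask(m)
  expect_equal(max(lab), 2)
  expect_equal(sort(tabulate(lab[lab > 0])), c(16, 36))

  diagm <- matrix(FALSE, 5, 5)
  diagm[cbind(1:4, 1:4)] <- TRUE  # corner-touching chain
  expect_equal(max(segment_mask(diagm)), 1)
})

test_that("the chain recovers exactly k regions on synthetic ellipses", {
  for (s in c(3, 4)) {
    k <- c(12, 30)[s - 2]
    sim <- simulate_nuclei_image(k, c(350, 350), c(80, 400), c(1, 2),
                                 background_noise_sd = 0.02, seed = s)
    nuc <- extract_nuclei(sim$image)
    expect_equal(nrow(nuc), k)
  }
})

test_that("shape descriptors reproduce circle and ellipse closed forms", {
  circ <- shape_descriptors(area = 25 * pi, perimeter = 10 * pi,
                            major_axis = 10, minor_axis = 10,
                            convex_area = 25 * pi)
  expect_equal(unname(circ), c(1, 1, 1, 1), tolerance = 1e-12)

  # ellipse semi-axes (10, 5): roundness = 4*50pi / (pi*20^2) = 0.5
  ell <- shape_descriptors(area = 50 * pi,
                           perimeter = 48.442,  # Ramanujan, irrelevant here
                           major_axis = 20, minor_axis = 10,
                           convex_area = 50 * pi)
  expect_equal(ell[["aspect_ratio"]], 2)
  expect_equal(ell[["roundness"]], 0.5, tolerance = 1e-12)
  expect_equal(ell[["solidity"]], 1)

  expect_error(shape_descriptors(10, 0, 5, 4, 10), "invalid")
  expect_error(shape_descriptors(10, 5, 4, 5, 10), "major_axis")
})

test_that("shape descriptors are scale invariant", {
  for (c_ in c(0.5, 2, 7)) {
    base <- shape_descriptors(80, 40, 14, 9, 90)
    scaled <- shape_descriptors(80 * c_^2, 40 * c_, 14 * c_, 9 * c_,
                                90 * c_^2)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("measured square geometry is exact", {
  m <- matrix(FALSE, 20, 20)
  m[6:15, 4:13] <- TRUE  # 10x10 square
  meas <- measure_regions(segment_mask(m))
  expect_equal(nrow(meas), 1)
  expect_equal(meas$area, 100)
  # centroid: cols 4:13 -> 0-based x 3..12 -> 7.5; rows 6:15 -> y 9.5
  expect_equal(meas$x, 7.5)
  expect_equal(meas$y, 9.5)
  expect_equal(meas$solidity, 1, tolerance = 1e-12)

  again <- measure_regions(segment_mask(m))
  expect_identical(meas, again)
})

test_that("moment axes recover ground-truth ellipse dimensions", {
  px <- rasterize_ellipse(40, 35, a = 12, b = 6, theta = 0.6,
                          shape = c(70, 80))
  lab <- segment_mask(pixels_to_mask(px, c(70, 80)))
  meas <- measure_regions(lab)
  expect_equal(meas$major_axis, 24, tolerance = 0.1 * 24)
  expect_equal(meas$minor_axis, 12, tolerance = 0.1 * 12)
  expect_equal(meas$area, length(px$x))
})

test_that("a rasterized disk measures as nearly circular", {
  px <- rasterize_ellipse(30, 30, 20, 20, 0, shape = c(61, 61))
  meas <- measure_regions(segment_mask(pixels_to_mask(px, c(61, 61))))
  raw_circ <- 4 * pi * meas$area / meas$perimeter^2
  raw_round <- 4 * meas$area / (pi * meas$major_axis^2)
  expect_gte(raw_circ, 0.9)
  expect_lte(meas$circularity, 1)
  expect_gte(raw_round, 0.95)
  expect_lte(raw_round, 1.05)
  expect_equal(meas$aspect_ratio, 1, tolerance = 0.02)
})

test_that("single-pixel regions are dropped as degenerate", {
  m <- matrix(FALSE, 8, 8); m[3, 3] <- TRUE; m[6, 5:7] <- TRUE
  expect_warning(meas <- measure_regions(segment_mask(m)),
                 "single-pixel")
  expect_equal(nrow(meas), 1)
  expect_equal(meas$area, 3)
})

test_that("the nucleus filter applies inclusive area and strict circularity bounds", {
  m <- fake_measurements(c(49, 50, 500, 501),
                         circularity = rep(0.9, 4))
  kept <- filter_nuclei(m)
  expect_equal(kept$area, c(50, 500))

  at_bound <- fake_measurements(c(100, 100),
                                circularity = c(0.3, 0.300001))
  expect_equal(nrow(filter_nuclei(at_bound)), 1)

  set.seed(44)
  big <- fake_measurements(runif(1000, 0, 600),
                           circularity = runif(1000))
  kept <- filter_nuclei(big)
  manual <- 0L
  for (i in seq_len(nrow(big)))
    if (big$area[i] >= 50 && big$area[i] <= 500 &&
        big$circularity[i] > 0.3) manual <- manual + 1L
  expect_equal(nrow(kept), manual)
  # idempotent, subset, order preserved
  expect_identical(filter_nuclei(kept), kept)
  expect_true(all(rownames(kept) %in% rownames(big)))
  expect_false(is.unsorted(as.integer(rownames(kept))))
})
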