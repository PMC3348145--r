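# Independent brute-force oracles used across tests. These deliberately
# re-derive each quantity from first principles and must stay free of
# the package's own code paths.

# BH step-up by direct definition: q_i = min_{j: p_j >= p_i over ranks}
# of p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    r <- which(o == i)  # rank of p[i]
    q[i] <- min(1, min(p[o][r:m] * m / (r:m)))
  }
  q
}

# Product-limit estimator tabulated by hand at each distinct event time.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = tt, surv = surv,
       median = if (any(surv <= 0.5)) tt[which(surv <= 0.5)[1]]
                else NA_real_)
}

# Two-group log-rank statistic from the classic O-E event table with
# hypergeometric variance.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# AUC as the fraction of concordant (positive, negative) pairs, ties
# counted half, by double loop.
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Welch two-sided t-test p-value via stats::t.test, one feature at a
# time (the package path is a vectorized reimplementation).
oracle_welch_p <- function(x, y) stats::t.test(x, y)$p.value

# Rasterize an ellipse on pixel centres (0-based coords); returns the
# pixel coordinate list (x, y) inside the ellipse.
rasterize_ellipse <- function(cx, cy, a, b, theta = 0, shape = NULL) {
  if (is.null(shape)) shape <- c(ceiling(cy + a + 3), ceiling(cx + a + 3))
  xs <- 0:(shape[2] - 1); ys <- 0:(shape[1] - 1)
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  list(x = g$x[inside], y = g$y[inside], shape = shape)
}

# Label matrix (1-based matrix indexing) from a 0-based pixel list.
pixels_to_mask <- function(px, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[cbind(px$y + 1, px$x + 1)] <- TRUE
  m
}

# Measurement rows with the columns build_profile expects, for profile
# arithmetic oracles.
fake_measurements <- function(areas,
                              perimeter = 2 * sqrt(pi * areas),
                              circularity = rep(1, length(areas)),
                              aspect_ratio = rep(1, length(areas)),
                              solidity = rep(1, length(areas)),
                              roundness = rep(1, length(areas)),
                              x = seq_along(areas) * 10,
                              y = seq_along(areas) * 10) {
  data.frame(area = areas, perimeter = perimeter,
             circularity = circularity, aspect_ratio = aspect_ratio,
             solidity = solidity, roundness = roundness, x = x, y = y)
}
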