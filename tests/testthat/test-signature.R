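test_that("gene prescreen equals its two-predicate brute force", {
  sim <- simulate_expression(40, 1000, 0, 0, noise_sd = 0.5, seed = 6)
  m <- sim$matrix
  m[1, ] <- 5  # constant gene
  expect_identical(prescreen_genes(m, 0, 0), m)
  kept <- prescreen_genes(m, 0.3, 0.3)
  expect_false("gene_00001" %in% rownames(kept))

  sds <- apply(m, 1, sd); meds <- apply(m, 1, median)
  manual <- rownames(m)[sds > quantile(sds, 0.3) &
                        meds > quantile(meds, 0.3)]
  expect_setequal(rownames(kept), manual)
})

test_that("snr matches its formula and is antisymmetric", {
  expect_equal(snr(c(1, 2, 3), c(2, 1, 3)), 0)
  expect_equal(snr(c(1, 2), c(3, 4)), -sqrt(2), tolerance = 1e-10)
  set.seed(1)
  x <- rnorm(20); y <- rnorm(15, 1)
  expect_equal(snr(x, y), -snr(y, x))
  expect_equal(snr(x, y), (mean(x) - mean(y)) / (sd(x) + sd(y)))
  expect_error(snr(c(1, 1), c(1, 1)), "degenerate")
  expect_error(snr(1, c(1, 2)), "at least 2")
})

test_that("BH adjustment equals the hand step-up and stats::p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_equal(bh_adjust(0.42), 0.42)
  for (s in 1:5) {
    set.seed(s)
    p <- runif(37)^2
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-12))
    # significance order preserved: q non-decreasing along increasing p
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
  # missing values propagate without affecting m
  p <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.04))
})

test_that("morph feature selection equals a brute-force t-test/BH loop", {
  g <- simulate_feature_matrix(n_samples = 60, n_features = 40,
                               n_informative = 6, n_up = 3,
                               shift = 1.2, seed = 13)
  sel <- select_morph_features(g$features, g$labels, fdr_max = 0.1)
  # oracle: per-feature Welch t, BH, threshold, order by SNR
  m <- t(as.matrix(g$features))
  is1 <- g$labels == "sensitive"
  p <- apply(m, 1, function(v) oracle_welch_p(v[is1], v[!is1]))
  q <- setNames(oracle_bh(p), names(p))
  w <- apply(m, 1, function(v) snr(v[is1], v[!is1]))
  manual <- names(which(q <= 0.1))
  expect_setequal(sel$feature, manual)
  expect_equal(sel$feature, manual[order(-w[manual])])
  expect_equal(sel$p, unname(p[sel$feature]), tolerance = 1e-10)
  expect_equal(sel$w, unname(w[sel$feature]), tolerance = 1e-10)
})

test_that("a feature identical across classes is never selected", {
  g <- simulate_feature_matrix(n_samples = 50, n_features = 20,
                               n_informative = 0, n_up = 0, seed = 3)
  f <- g$features
  f[, 1] <- rep(c(1, 2), length.out = 50)  # same values in any class
  sel <- select_morph_features(f, g$labels, fdr_max = 0.5)
  expect_false(colnames(f)[1] %in% sel$feature)
})

test_that("gene selection equals its two-predicate brute force", {
  sim <- simulate_expression(80, 100, 20, log2_fold_change = 1,
                             noise_sd = 0.5, n_up = 8, seed = 17)
  sel <- select_genes(sim$matrix, sim$labels, fold_change_cutoff = 1.5,
                      p_max = 0.05)
  is1 <- sim$labels == "sensitive"
  manual <- character(0)
  for (gname in rownames(sim$matrix)) {
    v <- sim$matrix[gname, ]
    lfc <- mean(v[!is1]) - mean(v[is1])
    pv <- oracle_welch_p(v[is1], v[!is1])
    if (abs(lfc) >= log2(1.5) && pv < 0.05)
      manual <- c(manual, gname)
  }
  expect_setequal(sel$feature, manual)

  # cutoff 1.0 reduces to the pure t-test rule
  sel1 <- select_genes(sim$matrix, sim$labels, 1.0, 0.05)
  pall <- apply(sim$matrix, 1, function(v)
    oracle_welch_p(v[is1], v[!is1]))
  expect_setequal(sel1$feature, names(which(pall < 0.05)))
})

test_that("planted genes are recovered with their planted directions", {
  sim <- simulate_expression(100, 300, 20, log2_fold_change = 2,
                             noise_sd = 0.5, n_up = 7, seed = 23)
  sel <- select_genes(sim$matrix, sim$labels, fold_change_cutoff = 2.5,
                      p_max = 1e-4)
  expect_setequal(sel$feature, sim$truth$informative)
  # w > 0 <=> higher in sensitive <=> planted direction +1
  dir_hat <- setNames(ifelse(sel$w > 0, 1, -1), sel$feature)
  expect_equal(dir_hat[sim$truth$informative],
               sim$truth$direction[sim$truth$informative],
               ignore_attr = TRUE)
  expect_equal(sum(sel$w > 0), 7)
  # fold change is the geometric-mean ratio resistant/sensitive
  g1 <- sel$feature[1]
  v <- sim$matrix[g1, ]
  expect_equal(sel$fold_change[1],
               2^(mean(v[sim$labels == "resistant"]) -
                  mean(v[sim$labels == "sensitive"])),
               tolerance = 1e-12)
})

test_that("signature entries satisfy their structural invariants", {
  sim <- simulate_expression(60, 150, 15, 1.5, 0.5, seed = 29)
  sel <- select_genes(sim$matrix, sim$labels, 1.2, 0.05)
  expect_gt(nrow(sel), 0)
  expect_equal(sign(sel$w), sign(sel$mu_sensitive - sel$mu_resistant))
  expect_true(all(sel$b >= pmin(sel$mu_sensitive, sel$mu_resistant) &
                  sel$b <= pmax(sel$mu_sensitive, sel$mu_resistant)))
})

test_that("fold-change tuning returns the accuracy-maximizing cutoff", {
  sim <- simulate_expression(80, 200, 20, log2_fold_change = 1.5,
                             noise_sd = 0.4, seed = 31)
  one <- tune_fold_change_cutoff(sim$matrix, sim$labels, 1.3)
  expect_equal(one$best_cutoff, 1.3)
  expect_equal(nrow(one$curve), 1)

  res <- tune_fold_change_cutoff(sim$matrix, sim$labels,
                                 c(1, 1.2, 1.5, 2, 4, 16))
  expect_true(all(res$curve$accuracy >= 0 & res$curve$accuracy <= 1))
  expect_equal(res$best_cutoff,
               res$curve$cutoff[which.max(res$curve$accuracy)])
  # an absurd cutoff selects nothing and is flagged at majority accuracy
  big <- res$curve[res$curve$cutoff == 16, ]
  expect_true(big$degenerate)
  expect_equal(big$accuracy, max(table(sim$labels)) / 80)

  # resubstitution accuracy equals an independent select/fit/score loop
  for (ct in c(1.2, 2)) {
    sel <- select_genes(sim$matrix, sim$labels, ct, 0.05)
    fit <- wv_fit(sim$matrix, sim$labels, sel)
    acc <- mean(predict(fit, sim$matrix, type = "class",
                        cutoff = 0) == sim$labels)
    expect_equal(res$curve$accuracy[res$curve$cutoff == ct], acc)
  }

  # under leave-one-out, cutoffs that exclude noise-scale fold changes
  # classify at least as well as keeping every nominally significant
  # gene (planted signal carries the information)
  acc_all <- acc_strong <- 0
  for (s in 1:4) {
    sim2 <- simulate_expression(40, 500, 10, log2_fold_change = 2,
                                noise_sd = 1, resistant_fraction = 0.35,
                                seed = s)
    r2 <- tune_fold_change_cutoff(sim2$matrix, sim2$labels, c(1, 2),
                                  method = "loo")
    acc_all <- acc_all + r2$curve$accuracy[r2$curve$cutoff == 1]
    acc_strong <- acc_strong + r2$curve$accuracy[r2$curve$cutoff == 2]
  }
  expect_gte(acc_strong, acc_all)
})

test_that("weighted-voting fit stores per-class means and midpoints", {
  sim <- simulate_expression(60, 50, 10, 1, 0.5, seed = 37)
  fit <- wv_fit(sim$matrix, sim$labels)
  is1 <- sim$labels == "sensitive"
  for (i in c(1, 25, 50)) {
    v <- sim$matrix[fit$entries$feature[i], ]
    expect_equal(fit$entries$mu_sensitive[i], mean(v[is1]))
    expect_equal(fit$entries$mu_resistant[i], mean(v[!is1]))
    expect_equal(fit$entries$b[i], (mean(v[is1]) + mean(v[!is1])) / 2)
    expect_equal(fit$entries$w[i], snr(v[is1], v[!is1]))
  }
  refit <- wv_fit(sim$matrix, sim$labels)
  expect_identical(fit$entries, refit$entries)

  # degenerate gene excluded with a warning
  m2 <- sim$matrix; m2[3, ] <- 7
  expect_warning(fit2 <- wv_fit(m2, sim$labels), "degenerate")
  expect_false(rownames(m2)[3] %in% fit2$entries$feature)
})

test_that("predictive scores follow the weighted-voting formula", {
  fit <- structure(list(entries = data.frame(
    feature = c("g1", "g2"), w = c(1, -1),
    mu_sensitive = c(2, 0), mu_resistant = c(0, 2), b = c(1, 1)),
    score_cutoff = 0, normalize = TRUE), class = "wv_model")
  expect_equal(unname(predict(fit, c(g1 = 2, g2 = 0))), 1)
  expect_equal(unname(predict(fit, c(g1 = 1, g2 = 1))), 0)
  expect_equal(unname(predict(fit, c(g1 = 2, g2 = 0), type = "class")),
               "sensitive")
  expect_equal(unname(predict(fit, c(g1 = 0, g2 = 2), type = "class")),
               "resistant")
  # reflection about the midpoints negates the score
  x <- c(g1 = 3.2, g2 = -0.4)
  refl <- 2 * c(g1 = 1, g2 = 1) - x
  expect_equal(unname(predict(fit, refl)), -unname(predict(fit, x)))
  # missing model gene: renormalized with a warning; none: error
  expect_warning(s <- predict(fit, c(g1 = 3)), "renormalized")
  expect_equal(unname(s), 1 * (3 - 1) / 1)
  expect_error(predict(fit, c(zz = 1)), "no model genes")
})

test_that("ROC agrees with pair counting and calibrates a sane cutoff", {
  # perfect separation
  r <- roc_cutoff(c(1, 2, 3, 10, 11, 12),
                  rep(c("resistant", "sensitive"), each = 3))
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  for (s in 1:5) {
    set.seed(s)
    sc <- round(rnorm(40), 1)  # rounding forces ties
    lb <- sample(rep(c("sensitive", "resistant"), c(25, 15)))
    r <- roc_cutoff(sc, lb)
    expect_equal(r$auc, oracle_auc(sc, lb == "sensitive"),
                 tolerance = 1e-10)
    # chosen cutoff maximizes Youden's J over all thresholds
    j <- vapply(unique(sc), function(t)
      mean(sc[lb == "sensitive"] > t) +
        mean(sc[lb == "resistant"] <= t) - 1, 0)
    expect_equal(r$sensitivity + r$specificity - 1, max(j),
                 tolerance = 1e-10)
  }

  if (requireNamespace("pROC", quietly = TRUE)) {
    set.seed(9)
    sc <- rnorm(60); lb <- sample(rep(c("sensitive", "resistant"), 30))
    r <- roc_cutoff(sc, lb)
    pr <- pROC::roc(response = lb, predictor = sc, levels =
                      c("resistant", "sensitive"), direction = "<",
                    quiet = TRUE)
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
  }

  # labels independent of scores: AUC near 0.5
  set.seed(100)
  sc <- rnorm(400); lb <- sample(rep(c("sensitive", "resistant"), 200))
  expect_equal(roc_cutoff(sc, lb)$auc, 0.5, tolerance = 0.1)

  # constant scores degenerate
  rd <- roc_cutoff(rep(1, 10), rep(c("sensitive", "resistant"), 5))
  expect_true(rd$degenerate)
  expect_equal(rd$auc, 0.5)

  # a supplied cutoff is honored
  rf <- roc_cutoff(c(-1, -0.5, 0.2, 0.4), c("resistant", "resistant",
                                            "sensitive", "sensitive"),
                   cutoff = -0.16)
  expect_equal(rf$cutoff, -0.16)
  expect_equal(rf$sensitivity, 1)
})

test_that("quantile splits reproduce the published 171/73 partition", {
  sp10 <- split_by_quantile(rnorm(10), 0.7)
  expect_equal(sum(sp10 == "high"), 7)
  expect_equal(sum(sp10 == "low"), 3)
  sp <- split_by_quantile(rnorm(244), 0.701)
  expect_equal(sum(sp == "high"), 171)
  expect_equal(sum(sp == "low"), 73)
  for (n in c(7, 53, 244)) {
    sp <- split_by_quantile(rnorm(n), 0.41)
    expect_length(sp, n)
    expect_equal(sum(sp == "high") + sum(sp == "low"), n)
  }
  # ties broken by stable sample order
  sp <- split_by_quantile(c(a = 1, b = 1, c = 1, d = 0), 0.5)
  expect_equal(sp[["a"]], "high")
  expect_equal(sp[["b"]], "high")
  expect_equal(sp[["c"]], "low")
})

test_that("Jarque-Bera is calibrated under normality and powered against skew", {
  pvals <- vapply(1:100, function(s) {
    set.seed(s); jarque_bera(rnorm(5000))$p_value
  }, 0)
  expect_gte(mean(pvals > 0.01), 0.95)

  set.seed(7)
  expect_lt(jarque_bera(rexp(500))$p_value, 0.01)
  expect_gte(jarque_bera(rnorm(100))$statistic, 0)
  expect_error(jarque_bera(rep(2, 50)), "constant")
  expect_error(jarque_bera(rnorm(5)), "at least 8")
})

test_that("the printed operating point implies the printed accuracy", {
  acc <- operating_point_accuracy(0.952, 0.70, 165, 67)
  expect_equal(round(100 * acc, 1), 87.9)
})
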