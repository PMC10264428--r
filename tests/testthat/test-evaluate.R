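test_that("metric formulas match direct recomputation on random matrices", {
  expect_equal(unname(cm_metrics(structure(
    list(TP = 1, FP = 0, TN = 1, FN = 0, positive = "REM"),
    class = "confusion_matrix"))), c(100, 100, 100))
  cm0 <- structure(list(TP = 0, FP = 0, TN = 90, FN = 10, positive = "REM"),
                   class = "confusion_matrix")
  m0 <- cm_metrics(cm0)
  expect_equal(unname(m0), c(90, 0, 100))

  set.seed(30)
  for (i in 1:50) {
    v <- as.list(rpois(4, 20) + 1)
    names(v) <- c("TP", "FP", "TN", "FN")
    cm <- structure(c(v, positive = "REM"), class = "confusion_matrix")
    m <- cm_metrics(cm)
    tot <- v$TP + v$FP + v$TN + v$FN
    expect_equal(m[["accuracy"]], 100 * (v$TP + v$TN) / tot)
    expect_equal(m[["sensitivity"]], 100 * v$TP / (v$TP + v$FN))
    expect_equal(m[["specificity"]], 100 * v$TN / (v$TN + v$FP))
    # sensitivity + FNR = 100 exactly
    expect_identical(m[["sensitivity"]] + (100 - m[["sensitivity"]]), 100)
  }
  # zero denominators are flagged undefined, not silently 0
  cmu <- confusion_matrix(c("WAKE", "WAKE"), c("WAKE", "REM"))
  expect_true(is.na(cm_metrics(cmu)[["sensitivity"]]))
})

test_that("confusion_matrix counts with REM positive", {
  cm <- confusion_matrix(c("REM", "REM", "WAKE", "WAKE", "WAKE"),
                         c("REM", "WAKE", "WAKE", "REM", "WAKE"))
  expect_equal(c(cm$TP, cm$FN, cm$FP, cm$TN), c(1, 1, 1, 2))
})

test_that("ROC/AUC basics and pair-concordance oracle", {
  r <- roc_and_auc(c(0.9, 0.8, 0.1, 0.2), c("REM", "REM", "WAKE", "WAKE"))
  expect_equal(r$auc, 1)
  expect_equal(roc_and_auc(rep(0.5, 6), c("REM", "REM", "WAKE", "WAKE", "WAKE", "WAKE"))$auc, 0.5)
  expect_error(roc_and_auc(1:3 / 3, rep("REM", 3)), "both positive and negative")

  set.seed(31)
  for (i in 1:100) {
    n <- sample(8:30, 1)
    y <- sample(c("REM", "WAKE"), n, TRUE)
    while (length(unique(y)) < 2) y <- sample(c("REM", "WAKE"), n, TRUE)
    s <- round(runif(n), 2)  # induce ties
    auc <- roc_and_auc(s, y)$auc
    pos <- s[y == "REM"]; neg <- s[y == "WAKE"]
    conc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(auc, conc, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(32)
  y <- sample(c("REM", "WAKE"), 60, TRUE)
  s <- rnorm(60)
  a0 <- roc_and_auc(s, y)$auc
  expect_equal(roc_and_auc(exp(s), y)$auc, a0)
  expect_equal(roc_and_auc(atan(3 * s + 1), y)$auc, a0)
})

test_that("repeated evaluation: perfect separation, determinism, redraw logic", {
  f <- make_gauss_features(n = 300, d = 2, sep = 12, rem_frac = 0.1, seed = 33)
  ev <- repeated_evaluation(f$x, f$y, n_shuffles = 5, seed = 1)
  expect_equal(unname(ev$mean), c(100, 100, 100))
  expect_equal(unname(ev$sd), c(0, 0, 0))

  ev1 <- repeated_evaluation(f$x, f$y, n_shuffles = 2, seed = 9)
  ev2 <- repeated_evaluation(f$x, f$y, n_shuffles = 2, seed = 9)
  expect_identical(ev1$per_shuffle, ev2$per_shuffle)

  # rare positive class: splits lacking REM in train/test must be redrawn
  f2 <- make_gauss_features(n = 80, d = 2, sep = 5, rem_frac = 0.01, seed = 34)
  ev3 <- repeated_evaluation(f2$x, f2$y, n_shuffles = 20, seed = 2)
  expect_false(anyNA(ev3$per_shuffle$sensitivity))
})

test_that("majority collapse: vanishing separation sends sensitivity to 0", {
  f <- make_gauss_features(n = 1000, d = 3, sep = 0, rem_frac = 0.05, seed = 35)
  ev <- repeated_evaluation(f$x, f$y, n_shuffles = 10, seed = 4)
  expect_lt(ev$mean[["sensitivity"]], 15)
  expect_gt(ev$mean[["accuracy"]], 90)   # accuracy alone hides the collapse
  expect_gt(ev$mean[["specificity"]], 90)
})

test_that("band ablation: uninformative feature -> FNR ~ 100, informative -> low", {
  set.seed(36)
  n <- 800
  y <- ifelse(runif(n) < 0.06, "REM", "WAKE")
  x <- cbind(flat = rnorm(n),                      # identical distribution
             good = rnorm(n) + ifelse(y == "REM", -5, 0))
  ab <- band_ablation_fnr(x, y, n_shuffles = 8, seed = 5)
  expect_gte(ab$mean_fnr[ab$band == "flat"], 95)
  expect_lte(ab$mean_fnr[ab$band == "good"], 10)
  expect_equal(ab$mean_fnr, 100 - ab$mean_sensitivity)
})

test_that("hourly correlation matches cor.test to 1e-9", {
  set.seed(37)
  hs <- data.frame(hour = 0:22, hour_of_day = (9 + 0:22) %% 24,
                   pct_wake = runif(23, 20, 80), pct_rem = runif(23, 0, 10))
  hs$`80-120Hz` <- 0.05 * hs$pct_wake + rnorm(23, 0, 0.5)
  hs$`200-350Hz` <- rnorm(23)
  hc <- suppressWarnings(hourly_correlation(hs))
  for (r in seq_len(nrow(hc))) {
    yv <- if (hc$state[r] == "WAKE") hs$pct_wake else hs$pct_rem
    ct <- cor.test(hs[[hc$band[r]]], yv)
    expect_equal(hc$r[r], unname(ct$estimate), tolerance = 1e-9)
    expect_equal(hc$p[r], ct$p.value, tolerance = 1e-9)
    expect_equal(hc$ci_low[r], ct$conf.int[1], tolerance = 1e-9)
    expect_equal(hc$ci_high[r], ct$conf.int[2], tolerance = 1e-9)
    expect_equal(hc$r_squared[r], unname(ct$estimate)^2, tolerance = 1e-9)
  }
  # exact linear relation
  hs2 <- hs; hs2$`80-120Hz` <- hs2$pct_wake
  hc2 <- suppressWarnings(hourly_correlation(hs2))
  expect_equal(hc2$r[hc2$band == "80-120Hz" & hc2$state == "WAKE"], 1)
  expect_error(suppressWarnings(hourly_correlation(transform(hs, pct_rem = 5))),
               "zero variance")
})

test_that("Mann-Whitney: exact enumeration equals brute force and wilcox.test", {
  set.seed(38)
  x <- c(1.2, 3.4, 0.2, 5.1)
  y <- c(2.2, 6.7, 4.4, 8.1, 7.3)
  mw <- mann_whitney_u(x, y)
  wt <- wilcox.test(x, y, exact = TRUE)
  expect_equal(mw$U, unname(wt$statistic))
  expect_equal(mw$p, wt$p.value, tolerance = 1e-12)

  # brute-force permutation distribution for n = (4, 5)
  pooled <- c(x, y); r <- rank(pooled)
  combos <- combn(9, 4)
  u_all <- colSums(matrix(r[combos], nrow = 4)) - 4 * 5 / 2
  u_obs <- sum(r[1:4]) - 10
  p_brute <- min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
  expect_equal(mw$p, p_brute, tolerance = 1e-12)

  # identical groups: no evidence
  expect_gt(mann_whitney_u(c(1, 2, 3, 4), c(1, 2, 3, 4))$p, 0.05)

  # large-sample path agrees with the tie-corrected normal approximation
  set.seed(39)
  a <- rnorm(40); b <- rnorm(45, 0.8)
  mw2 <- mann_whitney_u(a, b)
  wt2 <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw2$p, wt2$p.value, tolerance = 1e-9)
})

test_that("one-sample Wilcoxon signed-rank vs 100", {
  expect_error(wilcoxon_signed_rank(rep(100, 6)), "undefined")
  set.seed(40)
  x <- c(97.1, 99.2, 101.3, 95.4, 98.6, 96.2, 99.9, 94.8)  # distinct |x - 100|
  ws <- wilcoxon_signed_rank(x, mu = 100)
  wt <- wilcox.test(x, mu = 100, exact = TRUE)
  expect_equal(ws$V, unname(wt$statistic))
  expect_equal(ws$p, wt$p.value, tolerance = 1e-12)
  # large-sample path
  y <- rnorm(40, 99, 2)
  ws2 <- wilcoxon_signed_rank(y, mu = 100, exact_max = 10)
  wt2 <- wilcox.test(y, mu = 100, exact = FALSE, correct = TRUE)
  expect_equal(ws2$p, wt2$p.value, tolerance = 1e-9)
})

test_that("shuffle means stabilize by 200 shuffles", {
  f <- make_gauss_features(n = 500, d = 3, sep = 1.5, rem_frac = 0.1, seed = 41)
  ev <- repeated_evaluation(f$x, f$y, n_shuffles = 200, seed = 6)
  se <- ev$sd / sqrt(ev$meta$n_shuffles)
  expect_lt(se[["accuracy"]], 0.5)
  expect_lt(se[["specificity"]], 0.5)
})
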