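test_that("band table defaults and validation", {
  tab <- band_table()
  expect_equal(nrow(tab), 9)
  expect_equal(tab$low_hz[1], 0.1)
  expect_equal(tab$high_hz[9], 500)
  expect_error(band_table(c(1, 2), c(3, 4)), "non-overlapping")
  expect_error(band_table(5, 4), "low < high")
})

test_that("100 Hz unit sinusoid: its band gets 0.5, others are silent", {
  fs <- 1000
  t <- seq_len(4 * fs) / fs
  x <- sin(2 * pi * 100 * t)
  p <- sapply(seq_len(9), function(b) {
    tab <- band_table()
    band_average_power(x, fs, c(tab$low_hz[b], tab$high_hz[b]), mode = "integrated")
  })
  expect_equal(p[6], 0.5, tolerance = 0.01)       # 80-120 Hz
  expect_true(all(p[-6] < 0.01 * p[6]))
  expect_error(band_average_power(x, fs, c(400, 600)), "Nyquist")
  expect_equal(band_average_power(numeric(4000) , fs, c(80, 120)), 0)
})

test_that("Parseval: the nine bands partition the signal variance", {
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(4000)
    tab <- band_table()
    tot <- sum(sapply(seq_len(9), function(b) {
      band_average_power(x, 1000, c(tab$low_hz[b], tab$high_hz[b]), mode = "integrated")
    }))
    v <- mean((x - mean(x))^2)
    expect_lt(abs(tot - v) / v, 0.02)
  }
})

test_that("scale equivariance: c x signal -> c^2 x band power", {
  set.seed(4)
  x <- rnorm(4000)
  p1 <- band_average_power(x, 1000, c(30, 80))
  p2 <- band_average_power(5 * x, 1000, c(30, 80))
  expect_equal(p2, 25 * p1, tolerance = 1e-12)
})

test_that("segmentation arithmetic and partition property", {
  x <- rnorm(4001)
  m <- segment_epochs(x, 1000, 4)
  expect_equal(dim(m), c(4000, 1))
  expect_identical(as.numeric(m), x[1:4000])
  y <- rnorm(12000)
  m2 <- segment_epochs(y, 1000, 4)
  expect_identical(as.numeric(m2), y)
  expect_error(segment_epochs(rnorm(10), 1000, 4), "shorter than one epoch")
})

test_that("artifact excision: spike window, interpolation, untouched outside", {
  fs <- 1000
  x <- rep(0, 2000)
  expect_equal(excise_artifacts(x, 1, fs)$intervals |> nrow(), 0)

  x[1000] <- 10
  out <- excise_artifacts(x, 5, fs, pad_ms = 50)
  expect_equal(out$intervals, cbind(start = 950L, end = 1050L))
  expect_equal(sum(out$excised_mask), 101)
  expect_true(all(out$signal == 0))

  set.seed(5)
  y <- rnorm(2000)
  y[700] <- 50
  out2 <- excise_artifacts(y, 10, fs)
  expect_identical(out2$signal[-(650:750)], y[-(650:750)])
  expect_error(excise_artifacts(rep(100, 100), 1, fs), "entire signal")
})

test_that("excision catches >=95% of injected ground-truth artifact samples", {
  cfg <- small_cfg(duration_hours = 0.5, seed = 6,
                   artifact_rate_per_wake_epoch = 0.5)
  hyp <- simulate_hypnogram(cfg)
  clean <- simulate_signals(hyp, cfg, channels = "eeg_v1")
  out <- inject_artifacts(clean, hyp, cfg)
  expect_gt(nrow(out$artifacts), 5)
  thr <- 6 * sd(clean$channels$eeg_v1)
  exc <- excise_artifacts(out$recording$channels$eeg_v1, thr, 1000)
  truth_idx <- unlist(lapply(seq_len(nrow(out$artifacts)), function(k) {
    i0 <- round(out$artifacts$onset_s[k] * 1000)
    i0 + seq_len(round(out$artifacts$duration_s[k] * 1000))
  }))
  expect_gte(mean(exc$excised_mask[truth_idx]), 0.95)
})

test_that("Grubbs replacement matches the stated examples", {
  r1 <- grubbs_replace(c(1, 2, 3, 4, 5))
  expect_identical(r1$outliers, integer(0))
  expect_equal(r1$series, c(1, 2, 3, 4, 5))

  r2 <- grubbs_replace(c(1, 1, 1, 1, 100))
  expect_identical(r2$outliers, 5L)
  expect_equal(r2$series, rep(1, 5))

  r3 <- grubbs_replace(rep(7, 10))
  expect_identical(r3$outliers, integer(0))

  expect_error(grubbs_replace(c(0, 1, 1e6, 1e12)), "degenerate")
  expect_error(grubbs_replace(c(1, 2)), "n0 >= 3")
})

test_that("Grubbs agrees with a brute-force oracle on 1000 random series", {
  set.seed(10)
  for (i in 1:1000) {
    n <- sample(8:25, 1)
    x <- rnorm(n)
    k <- sample(0:2, 1)
    if (k > 0) x[sample.int(n, k)] <- rnorm(k, 0, 15)
    expect_identical(grubbs_replace(x)$outliers, oracle_grubbs_indices(x))
  }
})

test_that("zscore contract and affine invariance", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(11)
  x <- rnorm(200)
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(3.7 * x + 42), z, tolerance = 1e-12)
  expect_error(zscore(rep(1, 5)), "zero-variance")
})

test_that("extract_features shapes, drop rule and z-score postconditions", {
  cfg <- small_cfg(duration_hours = 0.25, seed = 12,
                   artifact_rate_per_wake_epoch = 0)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg, channels = "eeg_v1")
  fm <- extract_features(rec, hyp)
  expect_equal(dim(fm$values), c(length(hyp$labels), 9))
  expect_length(fm$dropped_epochs, 0)
  expect_true(all(abs(colMeans(fm$values)) < 1e-9))
  expect_true(all(abs(apply(fm$values, 2, sd) - 1) < 1e-9))
  expect_false(anyNA(fm$values))

  # a dense burst covering 10% of epoch 3 gets that epoch dropped
  rec2 <- rec
  n0 <- 2 * 4000 + 1
  rec2$channels$eeg_v1[n0:(n0 + 399)] <-
    rec2$channels$eeg_v1[n0:(n0 + 399)] + 60 * sd(rec2$channels$eeg_v1)
  fm2 <- extract_features(rec2, hyp)
  expect_true(2 %in% fm2$dropped_epochs)  # 0-based index of epoch 3
  expect_equal(nrow(fm2$values), length(hyp$labels) - length(fm2$dropped_epochs))

  # post-z-score features are invariant to a global signal rescale
  rec3 <- rec
  rec3$channels$eeg_v1 <- 3 * rec3$channels$eeg_v1
  fm3 <- extract_features(rec3, hyp)
  expect_equal(fm3$values, fm$values, tolerance = 1e-9)

  expect_error(extract_features(rec, hypnogram(rep("WAKE", 10), 4)),
               "complete epochs")
})

test_that("hourly summary arithmetic", {
  lab <- rep("WAKE", 1800)
  lab[901:945] <- "REM"  # 45 REM epochs in hour 2
  hyp <- hypnogram(lab, 4)
  fm <- structure(
    list(values = matrix(rep(c(1, 3), each = 900), ncol = 1,
                         dimnames = list(NULL, "80-120Hz")),
         epoch_index = 0:1799, labels = lab,
         epoch_seconds = 4, start_hour_of_day = 9),
    class = "feature_matrix"
  )
  hs <- hourly_summary(fm, hyp)
  expect_equal(nrow(hs), 2)
  expect_equal(hs$pct_wake, c(100, 95))
  expect_equal(hs$pct_rem, c(0, 5))
  expect_equal(hs$`80-120Hz`, c(1, 3))
  expect_equal(hs$hour_of_day, c(9, 10))
})
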