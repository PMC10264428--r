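test_that("state vocabulary and alias mapping are stable", {
  expect_identical(vigilance_states(), c("WAKE", "NREM", "REM"))
  expect_identical(normalize_states(c("REMS", "nrems", "w", "Wake")),
                   c("REM", "NREM", "WAKE", "WAKE"))
  expect_error(normalize_states("DOZE"), "unknown vigilance state")
})

test_that("sim_config validates its invariants", {
  expect_error(sim_config(target_state_fractions = c(WAKE = 0.6, NREM = 0.5, REM = 0.05)),
               "sum to 1")
  expect_error(sim_config(emg_rms_per_state = c(WAKE = 1, NREM = 2, REM = 3)),
               "REM <= NREM <= WAKE")
  expect_error(sim_config(artifact_rate_per_wake_epoch = 1.5), "\\[0, 1\\]")
  g <- default_band_gains(); g[1, 1] <- -1
  expect_error(sim_config(band_gain_table = g), "non-negative")
})

test_that("simulated hypnogram is deterministic and hits the state budget", {
  cfg <- sim_config(seed = 1)
  hyp <- simulate_hypnogram(cfg)
  expect_length(hyp$labels, 20700)  # 23 h of 4-s epochs
  expect_identical(hyp$labels, simulate_hypnogram(cfg)$labels)
  f <- state_fractions(hyp)
  expect_lt(abs(f[["WAKE"]] - 0.47), 0.03)
  expect_lt(abs(f[["NREM"]] - 0.48), 0.03)
  expect_lt(abs(f[["REM"]] - 0.05), 0.03)
})

test_that("degenerate all-WAKE chain and fraction recovery", {
  cfg <- small_cfg(target_state_fractions = c(WAKE = 1, NREM = 0, REM = 0))
  expect_true(all(simulate_hypnogram(cfg)$labels == "WAKE"))

  # without circadian modulation the chain must recover its stationary law
  # within 3 SE, where the SE comes from the chain's integrated
  # autocovariance: var = (1/n) [pi (1-pi) + 2 sum_k (P^k_ii - pi_i) pi_i]
  cfg2 <- sim_config(duration_hours = 12, seed = 5,
                     circadian_amplitude = c(WAKE = 0, NREM = 0, REM = 0))
  hyp2 <- simulate_hypnogram(cfg2)
  f <- state_fractions(hyp2)
  P <- remhf:::transition_matrix(cfg2$target_state_fractions,
                                 cfg2$state_dwell_means_epochs)
  tgt <- cfg2$target_state_fractions
  n <- length(hyp2$labels)
  Pk <- P
  acov <- tgt * (1 - tgt)
  for (k in 1:5000) {
    acov <- acov + 2 * (diag(Pk) - tgt) * tgt
    Pk <- Pk %*% P
    if (max(abs(diag(Pk) - tgt)) < 1e-12) break
  }
  se <- sqrt(acov / n)
  for (s in vigilance_states()) {
    expect_lt(abs(f[[s]] - tgt[[s]]), 3 * se[[s]])
  }
})

test_that("circadian modulation puts more WAKE in the dark phase", {
  hyp <- simulate_hypnogram(sim_config(seed = 2))
  hod <- (9 + floor((seq_along(hyp$labels) - 1) * 4 / 3600)) %% 24
  dark <- !(hod >= 9 & hod < 21)
  expect_gt(mean(hyp$labels[dark] == "WAKE"), mean(hyp$labels[!dark] == "WAKE"))
  expect_gt(mean(hyp$labels[!dark] == "REM"), mean(hyp$labels[dark] == "REM"))
})

test_that("signals are deterministic and carry the configured spectral structure", {
  cfg <- small_cfg(duration_hours = 0.5, seed = 3)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg, channels = c("eeg_v1", "emg"))
  rec2 <- simulate_signals(hyp, cfg, channels = c("eeg_v1", "emg"))
  expect_identical(rec$channels$eeg_v1, rec2$channels$eeg_v1)

  fm <- extract_features(rec, hyp, zscore = FALSE, grubbs_alpha = NA,
                         artifact_threshold = 1e9)
  mw <- colMeans(fm$values[fm$labels == "WAKE", , drop = FALSE])
  mn <- colMeans(fm$values[fm$labels == "NREM", , drop = FALSE])
  mr <- colMeans(fm$values[fm$labels == "REM", , drop = FALSE])
  # 200-350 Hz: WAKE > NREM > REM by the default gain table
  expect_gt(mw[["200-350Hz"]], mn[["200-350Hz"]])
  expect_gt(mn[["200-350Hz"]], mr[["200-350Hz"]])
  # NREM delta dominance; REM theta over delta
  expect_gt(mn[["0.1-4Hz"]], mw[["0.1-4Hz"]])
  rem_ep <- which(hyp$labels == "REM")
  blocks <- segment_epochs(rec, epoch_seconds = 4)
  th <- mean(vapply(rem_ep, function(i) band_average_power(blocks[, i], 1000, c(6, 9)), 1))
  de <- mean(vapply(rem_ep, function(i) band_average_power(blocks[, i], 1000, c(1, 4)), 1))
  expect_gt(th, de)
  # EMG atonia ordering survives into per-epoch RMS
  met <- compute_epoch_metrics(rec)
  expect_lt(mean(met$emg_rms[hyp$labels == "REM"]),
            mean(met$emg_rms[hyp$labels == "WAKE"]))
})

test_that("all-zero configuration produces all-zero channels", {
  g <- default_band_gains(); g[] <- 0
  cfg <- small_cfg(
    duration_hours = 0.05,
    band_gain_table = g,
    oscillation_params = list(delta_band = c(1, 4), theta_band = c(6, 9),
                              delta_amp = c(WAKE = 0, NREM = 0, REM = 0),
                              theta_amp = c(WAKE = 0, NREM = 0, REM = 0)),
    one_over_f_scale = 0,
    emg_rms_per_state = c(WAKE = 0, NREM = 0, REM = 0)
  )
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg, channels = c("eeg_v1", "emg"))
  expect_true(all(rec$channels$eeg_v1 == 0))
  expect_true(all(rec$channels$emg == 0))
})

test_that("band power is monotone in the configured gain", {
  powers <- sapply(c(0.5, 1, 2), function(g) {
    tab <- default_band_gains()
    tab["NREM", "120-200Hz"] <- g
    cfg <- small_cfg(duration_hours = 100 * 4 / 3600, seed = 21,
                     band_gain_table = tab)
    hyp <- hypnogram(rep("NREM", 100), 4)
    rec <- simulate_signals(hyp, cfg, channels = "eeg_v1")
    blocks <- segment_epochs(rec, epoch_seconds = 4)
    mean(vapply(seq_len(ncol(blocks)),
                function(i) band_average_power(blocks[, i], 1000, c(120, 200)), 1))
  })
  expect_identical(order(powers), 1:3)
  expect_equal(cor(powers, c(0.5, 1, 2), method = "spearman"), 1)
})

test_that("artifact injection respects rate and raises epoch peaks", {
  cfg <- small_cfg(duration_hours = 0.5, seed = 4,
                   artifact_rate_per_wake_epoch = 0)
  hyp <- simulate_hypnogram(cfg)
  rec <- simulate_signals(hyp, cfg, channels = "eeg_v1")
  out0 <- inject_artifacts(rec, hyp, cfg)
  expect_identical(out0$recording$channels$eeg_v1, rec$channels$eeg_v1)
  expect_equal(nrow(out0$artifacts), 0)

  cfg1 <- small_cfg(duration_hours = 0.5, seed = 4,
                    artifact_rate_per_wake_epoch = 1)
  out1 <- inject_artifacts(rec, hyp, cfg1)
  n_wake <- sum(hyp$labels == "WAKE")
  expect_equal(nrow(out1$artifacts), n_wake)
  expect_true(all(hyp$labels[out1$artifacts$epoch_index + 1] == "WAKE"))

  clean_peaks <- apply(abs(segment_epochs(rec, epoch_seconds = 4)), 2, max)
  dirty <- segment_epochs(out1$recording, epoch_seconds = 4)
  art_peaks <- apply(abs(dirty[, out1$artifacts$epoch_index + 1, drop = FALSE]), 2, max)
  expect_true(all(art_peaks > quantile(clean_peaks, 0.999)))
})
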