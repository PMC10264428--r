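#' Scoring thresholds
#'
#' Manual thresholds for semi-automated vigilance-state scoring from EMG RMS
#' and EEG delta/theta activity.
#'
#' @param emg_rms EMG RMS threshold (signal units).
#' @param delta_power delta-band (0.1-4 Hz) average-power threshold.
#' @param theta_power theta-band average-power threshold.
#' @return Object of class `scoring_thresholds`.
#' @export
scoring_thresholds <- function(emg_rms, delta_power, theta_power) {
  stopifnot(emg_rms > 0, delta_power > 0, theta_power > 0)
  structure(list(emg_rms = emg_rms, delta_power = delta_power,
                 theta_power = theta_power),
            class = "scoring_thresholds")
}

#' Per-epoch scoring metrics
#'
#' Computes, for every consecutive epoch: the EMG root-mean-square and the
#' EEG delta- and theta-band average power (via [band_average_power()]) on
#' the designated EEG channel.
#'
#' @param recording a [recording()] with at least one EEG and one EMG
#'   channel.
#' @param epoch_seconds epoch length (s).
#' @param eeg_channel EEG channel used for delta/theta (default first EEG
#'   channel; conventionally the visual-cortex derivation).
#' @param delta_band,theta_band band edges in Hz. The theta default 4-8 Hz
#'   matches the feature table's theta band; rodent theta is sometimes taken
#'   as 6-9 Hz, so the edges are configurable.
#' @return Object of class `epoch_metrics`: data frame with `emg_rms`,
#'   `delta_power`, `theta_power`, one row per epoch.
#' @export
compute_epoch_metrics <- function(recording, epoch_seconds = 4,
                                  eeg_channel = NULL,
                                  delta_band = c(0.1, 4),
                                  theta_band = c(4, 8)) {
  stopifnot(inherits(recording, "recording"))
  emg_ch <- channels_with_role(recording, "emg")[1L]
  if (is.null(eeg_channel)) eeg_channel <- channels_with_role(recording, "eeg")[1L]
  fs <- recording$sampling_rate_hz
  emg <- segment_epochs(recording$channels[[emg_ch]], fs, epoch_seconds)
  eeg <- segment_epochs(recording$channels[[eeg_channel]], fs, epoch_seconds)
  n_per <- nrow(eeg)
  freq <- seq_len(n_per %/% 2L) * fs / n_per
  dbins <- band_bins(freq, delta_band[1], delta_band[2])
  tbins <- band_bins(freq, theta_band[1], theta_band[2])
  df <- fs / n_per
  eeg <- sweep(eeg, 2L, colMeans(eeg))
  # chunked periodogram to bound memory on long recordings
  n_epochs <- ncol(eeg)
  delta_p <- theta_p <- numeric(n_epochs)
  chunk <- 2048L
  nyq <- if (n_per %% 2L == 0L) n_per %/% 2L else -1L
  for (start in seq(1L, n_epochs, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_epochs)
    P <- Mod(stats::mvfft(eeg[, cols, drop = FALSE]))^2 * (2 / (fs * n_per))
    P <- P[2:(n_per %/% 2L + 1L), , drop = FALSE]
    if (nyq > 0L) P[nyq, ] <- P[nyq, ] / 2
    delta_p[cols] <- colSums(P[dbins, , drop = FALSE]) * df / diff(delta_band)
    theta_p[cols] <- colSums(P[tbins, , drop = FALSE]) * df / diff(theta_band)
  }
  structure(
    data.frame(emg_rms = sqrt(colMeans(emg^2)),
               delta_power = delta_p, theta_power = theta_p),
    class = c("epoch_metrics", "data.frame")
  )
}

#' Threshold scoring of epochs
#'
#' The semi-automated scoring rules: an epoch is WAKE when EMG RMS is at or
#' above its threshold (high muscle tone); with sub-threshold EMG it is NREM
#' when delta power is above its threshold, REM when delta is below
#' threshold and theta above its threshold. Epochs with sub-threshold EMG,
#' delta and theta match no rule; they are conservatively assigned WAKE
#' (REM requires positive theta evidence) and counted as `rule_gap` in the
#' result attributes.
#'
#' @param metrics an [compute_epoch_metrics()] result (or data frame with
#'   the same columns).
#' @param thresholds a [scoring_thresholds()].
#' @param epoch_seconds,start_hour_of_day hypnogram bookkeeping.
#' @return A [hypnogram()] with attribute `rule_gap` (number of epochs that
#'   matched no rule).
#' @export
threshold_score <- function(metrics, thresholds, epoch_seconds = 4,
                            start_hour_of_day = 9) {
  stopifnot(inherits(thresholds, "scoring_thresholds"))
  emg <- metrics$emg_rms
  delta <- metrics$delta_power
  theta <- metrics$theta_power
  stopifnot(length(emg) > 0, length(emg) == length(delta),
            length(emg) == length(theta))
  lab <- rep("WAKE", length(emg))
  sleepy <- emg < thresholds$emg_rms
  lab[sleepy & delta > thresholds$delta_power] <- "NREM"
  is_rem <- sleepy & delta <= thresholds$delta_power &
    theta > thresholds$theta_power
  lab[is_rem] <- "REM"
  gap <- sum(sleepy & delta <= thresholds$delta_power &
               theta <= thresholds$theta_power)
  out <- hypnogram(lab, epoch_seconds, start_hour_of_day)
  attr(out, "rule_gap") <- gap
  out
}

#' Absorb micro-states into their neighbours
#'
#' Vigilance-state runs shorter than `min_run_epochs` (3 by default) are not
#' regarded as genuine state changes; each such run is relabelled to the
#' preceding surviving state (a short leading run takes the following
#' state). The result contains no run shorter than `min_run_epochs` unless
#' the whole sequence is a single shorter run. Idempotent.
#'
#' @param hypnogram a [hypnogram()].
#' @param min_run_epochs minimum genuine run length (epochs).
#' @return A smoothed [hypnogram()].
#' @export
smooth_microstates <- function(hypnogram, min_run_epochs = 3L) {
  stopifnot(inherits(hypnogram, "hypnogram"), min_run_epochs >= 1L)
  lab <- hypnogram$labels
  if (length(lab) == 0L) stop("empty hypnogram")
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1L) break
    if (!any(r$lengths < min_run_epochs)) break
    # absorb the shortest (leftmost on ties) run first, so an isolated
    # micro-state vanishes before its flanking runs are considered
    i <- which.min(replace(r$lengths, r$lengths >= min_run_epochs, NA))
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    lab <- inverse.rle(r)
  }
  out <- hypnogram
  out$labels <- lab
  out
}

#' Midpoint threshold calibration (convenience, not a scoring rule)
#'
#' Given labelled calibration epochs, places each threshold midway between
#' the class-conditional metric means: EMG between wake and sleep, delta
#' between NREM and the rest, theta between REM and the rest. This is a
#' pragmatic stand-in for the manual threshold choice, not a published rule.
#'
#' @param metrics an [compute_epoch_metrics()] result.
#' @param labels vigilance-state labels, one per epoch.
#' @return A [scoring_thresholds()].
#' @export
calibrate_thresholds <- function(metrics, labels) {
  labels <- normalize_states(labels)
  stopifnot(nrow(metrics) == length(labels))
  need <- setdiff(vigilance_states(), unique(labels))
  if (length(need) > 0L) {
    stop("calibration data must contain all three states; missing: ",
         paste(need, collapse = ", "))
  }
  wake <- labels == "WAKE"; nrem <- labels == "NREM"; rem <- labels == "REM"
  scoring_thresholds(
    emg_rms = (mean(metrics$emg_rms[wake]) + mean(metrics$emg_rms[!wake])) / 2,
    delta_power = (mean(metrics$delta_power[nrem]) +
                     mean(metrics$delta_power[!nrem])) / 2,
    theta_power = (mean(metrics$theta_power[rem]) +
                     mean(metrics$theta_power[!rem])) / 2
  )
}

#' Cohen's kappa between two hypnograms
#'
#' Chance-corrected agreement between two label sequences of equal length.
#'
#' @param a,b hypnograms or label vectors.
#' @return Scalar kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(a, b) {
  la <- if (inherits(a, "hypnogram")) a$labels else normalize_states(a)
  lb <- if (inherits(b, "hypnogram")) b$labels else normalize_states(b)
  stopifnot(length(la) == length(lb), length(la) > 0)
  lv <- union(la, lb)
  tab <- table(factor(la, lv), factor(lb, lv))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}
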