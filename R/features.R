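#' The nine-band frequency table
#'
#' Default analysis bands spanning 0.1-500 Hz: the classical sleep bands
#' (delta, theta, alpha, beta, low gamma) plus four high-frequency bands
#' (80-120, 120-200, 200-350, 350-500 Hz) that carry most of the
#' REM-vs-wake discrimination.
#'
#' @param low_hz,high_hz numeric vectors of band edges; bands are half-open
#'   intervals `[low, high)`.
#' @return A data frame with columns `low_hz`, `high_hz` and class
#'   `band_table`.
#' @export
band_table <- function(low_hz = c(0.1, 4, 8, 13, 30, 80, 120, 200, 350),
                       high_hz = c(4, 8, 13, 30, 80, 120, 200, 350, 500)) {
  stopifnot(length(low_hz) == length(high_hz))
  if (any(low_hz >= high_hz)) stop("each band must have low < high")
  o <- order(low_hz)
  low_hz <- low_hz[o]; high_hz <- high_hz[o]
  if (any(head(high_hz, -1) > tail(low_hz, -1) + 1e-12)) {
    stop("bands must be non-overlapping")
  }
  structure(data.frame(low_hz = low_hz, high_hz = high_hz),
            class = c("band_table", "data.frame"))
}

#' @rdname band_table
#' @param bands a `band_table`.
#' @return `band_labels()`: character labels like `"0.1-4Hz"`.
#' @export
band_labels <- function(bands) {
  sprintf("%g-%gHz", bands$low_hz, bands$high_hz)
}

#' One-sided periodogram of a single epoch
#'
#' Single-taper periodogram after mean removal; no windowing or detrending
#' beyond the mean. At the default 4-s epoch and 1000 Hz this gives 0.25-Hz
#' resolution. Satisfies Parseval: `sum(psd) * df` equals the population
#' variance of the epoch.
#'
#' @param x numeric samples of one epoch.
#' @param fs sampling rate (Hz).
#' @return List with `freq` (Hz, excluding DC) and `psd` (power per Hz).
#' @export
epoch_psd <- function(x, fs) {
  n <- length(x)
  stopifnot(n >= 2L, fs > 0)
  X <- stats::fft(x - mean(x))
  half <- n %/% 2L
  k <- seq_len(half)
  p <- (2 / (fs * n)) * Mod(X[k + 1L])^2
  if (n %% 2L == 0L) p[half] <- p[half] / 2  # Nyquist bin is not doubled
  list(freq = k * fs / n, psd = p)
}

# indices of periodogram bins falling in [low, high)
band_bins <- function(freq, low, high) which(freq >= low & freq < high)

#' Average power in a frequency band
#'
#' Integrates the epoch periodogram over a half-open band `[low, high)`.
#' In `"average"` mode (default) the band-integrated power is divided by the
#' bandwidth, giving units of power per Hz and making bands of different
#' widths comparable; `"integrated"` returns the raw integral.
#'
#' @param epoch numeric samples of one epoch (artifact-excised).
#' @param fs sampling rate (Hz).
#' @param band numeric length-2 `(low, high)` in Hz; `high` must not exceed
#'   the Nyquist frequency.
#' @param mode `"average"` or `"integrated"`.
#' @return Non-negative scalar.
#' @export
band_average_power <- function(epoch, fs, band, mode = c("average", "integrated")) {
  mode <- match.arg(mode)
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (band[2] > fs / 2 + 1e-9) {
    stop("band upper edge ", band[2], " Hz exceeds Nyquist frequency ", fs / 2, " Hz")
  }
  pg <- epoch_psd(epoch, fs)
  df <- fs / length(epoch)
  p <- sum(pg$psd[band_bins(pg$freq, band[1], band[2])]) * df
  if (mode == "average") p / (band[2] - band[1]) else p
}

#' Segment a signal into fixed-length epochs
#'
#' @param x numeric vector, or a [recording()] (then `channel` selects one).
#' @param fs sampling rate (Hz); taken from the recording when given one.
#' @param epoch_seconds epoch length (s).
#' @param channel channel name when `x` is a recording.
#' @return Numeric matrix with `fs * epoch_seconds` rows, one column per
#'   complete epoch; a trailing partial epoch is dropped.
#' @export
segment_epochs <- function(x, fs = NULL, epoch_seconds = 4, channel = NULL) {
  if (inherits(x, "recording")) {
    fs <- x$sampling_rate_hz
    if (is.null(channel)) channel <- channels_with_role(x, "eeg")[1L]
    x <- x$channels[[channel]]
  }
  stopifnot(!is.null(fs))
  n_per <- round(fs * epoch_seconds)
  n_epochs <- length(x) %/% n_per
  if (n_epochs < 1L) stop("recording shorter than one epoch")
  matrix(x[seq_len(n_epochs * n_per)], nrow = n_per)
}

#' Excise threshold-crossing artifacts from a signal
#'
#' Every sample whose absolute value exceeds `threshold` marks an artifact
#' peak; the peak plus `pad_ms` before and after it (50 ms by default) is
#' replaced by linear interpolation between the flanking clean samples.
#' Overlapping excision windows are merged.
#'
#' @param signal numeric vector.
#' @param threshold positive amplitude threshold (signal units).
#' @param fs sampling rate (Hz).
#' @param pad_ms padding on each side of a peak (ms).
#' @return List with `signal` (cleaned copy), `intervals` (two-column matrix
#'   of sample start/end indices, possibly empty) and `excised_mask`
#'   (logical, TRUE where samples were replaced).
#' @export
excise_artifacts <- function(signal, threshold, fs, pad_ms = 50) {
  stopifnot(threshold > 0, pad_ms >= 0, fs > 0)
  n <- length(signal)
  peaks <- which(abs(signal) > threshold)
  if (length(peaks) == 0L) {
    return(list(signal = signal,
                intervals = matrix(integer(0), ncol = 2L,
                                   dimnames = list(NULL, c("start", "end"))),
                excised_mask = rep(FALSE, n)))
  }
  pad <- round(pad_ms / 1000 * fs)
  lo <- pmax(peaks - pad, 1L)
  hi <- pmin(peaks + pad, n)
  # merge overlapping/adjacent windows
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  keep_start <- c(TRUE, lo[-1L] > cummax(hi[-length(hi)]) + 1L)
  grp <- cumsum(keep_start)
  starts <- tapply(lo, grp, min)
  ends <- tapply(hi, grp, max)
  mask <- rep(FALSE, n)
  for (g in seq_along(starts)) mask[starts[g]:ends[g]] <- TRUE
  if (all(mask)) stop("entire signal exceeds the artifact threshold; nothing to interpolate from")
  clean_idx <- which(!mask)
  signal[mask] <- stats::approx(clean_idx, signal[clean_idx],
                                xout = which(mask), rule = 2)$y
  list(signal = signal,
       intervals = cbind(start = as.integer(starts), end = as.integer(ends)),
       excised_mask = mask)
}

#' Default artifact threshold from a robust SD
#'
#' The excision threshold is a manual per-recording choice in practice; this
#' helper returns `k` times the median-absolute-deviation estimate of the
#' signal SD, which is insensitive to the artifacts themselves.
#'
#' @param signal numeric vector.
#' @param k multiplier (default 6).
#' @return Positive scalar threshold.
#' @export
robust_artifact_threshold <- function(signal, k = 6) {
  k * stats::mad(signal)
}

# two-sided Grubbs critical value for sample size n at significance alpha
grubbs_critical <- function(n, alpha) {
  tcrit <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
}

#' Iterative Grubbs outlier replacement
#'
#' Applies the two-sided Grubbs test repeatedly, removing the single most
#' extreme point per iteration while the test rejects, then replaces every
#' flagged point by linear interpolation between its nearest non-outlier
#' neighbours (nearest-value extrapolation at the series ends). A constant
#' series (zero spread) is returned unchanged.
#'
#' @param series numeric vector, length >= 3.
#' @param alpha significance level of each Grubbs test (two-sided).
#' @return List with `series` (cleaned) and `outliers` (integer indices,
#'   possibly empty).
#' @export
grubbs_replace <- function(series, alpha = 0.05) {
  n0 <- length(series)
  stopifnot(n0 >= 3L, alpha > 0, alpha < 1)
  active <- seq_len(n0)
  out <- integer(0)
  repeat {
    n <- length(active)
    if (n < 3L) {
      stop("Grubbs iteration flagged all but two points; series is degenerate")
    }
    x <- series[active]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) break
    dev <- abs(x - mean(x))
    i <- which.max(dev)
    G <- dev[i] / s
    if (G <= grubbs_critical(n, alpha)) break
    out <- c(out, active[i])
    active <- active[-i]
  }
  if (length(out) > 0L) {
    out <- sort(out)
    series[out] <- stats::approx(active, series[active], xout = out, rule = 2)$y
  }
  list(series = series, outliers = out)
}

#' Standard score
#'
#' `(x - mean(x)) / sd(x)` with the sample SD (n-1 denominator).
#'
#' @param x numeric vector, length >= 2 with positive spread.
#' @return Numeric vector with mean 0 and sample SD 1.
#' @export
zscore <- function(x) {
  stopifnot(length(x) >= 2L)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("cannot z-score a zero-variance series")
  (x - mean(x)) / s
}

#' Extract the per-epoch band-power feature matrix
#'
#' The full feature pipeline for one EEG channel: artifact excision
#' (threshold crossing, peak +/- `pad_ms`), segmentation into consecutive
#' non-overlapping epochs, per-epoch periodogram band power in each of the
#' nine bands, per-band iterative Grubbs outlier replacement across epochs,
#' and per-band z-scoring across the recording. Epochs in which more than
#' `max_excised_fraction` of samples were excised are dropped (the
#' "more than 5% movement artifacts" exclusion, applied per epoch).
#'
#' @param recording a [recording()].
#' @param hypnogram the matching [hypnogram()]; labels are attached to rows.
#' @param bands a [band_table()].
#' @param channel EEG channel to analyse (default first EEG channel).
#' @param artifact_threshold amplitude threshold for excision; `NULL`
#'   (default) uses [robust_artifact_threshold()].
#' @param pad_ms excision padding around each artifact peak (ms).
#' @param max_excised_fraction drop epochs with more than this fraction of
#'   excised samples.
#' @param grubbs_alpha significance level for outlier replacement; `NA`
#'   skips the Grubbs step.
#' @param zscore standardize each band across epochs (default TRUE).
#' @param band_power_mode `"average"` (per-Hz) or `"integrated"` band power.
#' @return Object of class `feature_matrix`: list with `values` (epochs x
#'   bands matrix), `epoch_index` (0-based indices into the hypnogram),
#'   `labels`, `bands`, `channel`, `dropped_epochs`, `outliers` (per-band
#'   index list), `zscored`, `excised_intervals`.
#' @export
extract_features <- function(recording, hypnogram,
                             bands = band_table(),
                             channel = NULL,
                             artifact_threshold = NULL,
                             pad_ms = 50,
                             max_excised_fraction = 0.05,
                             grubbs_alpha = 0.05,
                             zscore = TRUE,
                             band_power_mode = c("average", "integrated")) {
  band_power_mode <- match.arg(band_power_mode)
  stopifnot(inherits(recording, "recording"), inherits(hypnogram, "hypnogram"))
  fs <- recording$sampling_rate_hz
  if (is.null(channel)) channel <- channels_with_role(recording, "eeg")[1L]
  sig <- recording$channels[[channel]]
  if (is.null(sig)) stop("recording has no channel named '", channel, "'")
  n_per <- round(fs * hypnogram$epoch_seconds)
  n_epochs <- length(sig) %/% n_per
  if (n_epochs != length(hypnogram$labels)) {
    stop("recording holds ", n_epochs, " complete epochs but hypnogram has ",
         length(hypnogram$labels), " labels")
  }
  if (max(bands$high_hz) > fs / 2 + 1e-9) {
    stop("band table exceeds the Nyquist frequency")
  }

  if (is.null(artifact_threshold)) {
    artifact_threshold <- robust_artifact_threshold(sig)
  }
  exc <- excise_artifacts(sig, artifact_threshold, fs, pad_ms)
  sig <- exc$signal

  # fraction of excised samples per epoch decides the drop rule
  excised_frac <- colMeans(matrix(exc$excised_mask[seq_len(n_epochs * n_per)],
                                  nrow = n_per))
  keep <- excised_frac <= max_excised_fraction

  freq <- seq_len(n_per %/% 2L) * fs / n_per
  bins <- lapply(seq_len(nrow(bands)),
                 function(b) band_bins(freq, bands$low_hz[b], bands$high_hz[b]))
  widths <- bands$high_hz - bands$low_hz
  df <- fs / n_per

  values <- matrix(NA_real_, nrow = n_epochs, ncol = nrow(bands),
                   dimnames = list(NULL, band_labels(bands)))
  chunk <- 1024L
  nyq <- if (n_per %% 2L == 0L) n_per %/% 2L else -1L
  for (start in seq(1L, n_epochs, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n_epochs)
    block <- matrix(sig[((cols[1L] - 1L) * n_per + 1L):(cols[length(cols)] * n_per)],
                    nrow = n_per)
    block <- sweep(block, 2L, colMeans(block))
    P <- Mod(stats::mvfft(block))^2 * (2 / (fs * n_per))
    P <- P[2:(n_per %/% 2L + 1L), , drop = FALSE]
    if (nyq > 0L) P[nyq, ] <- P[nyq, ] / 2
    for (b in seq_along(bins)) {
      p <- colSums(P[bins[[b]], , drop = FALSE]) * df
      values[cols, b] <- if (band_power_mode == "average") p / widths[b] else p
    }
  }

  values <- values[keep, , drop = FALSE]
  epoch_index <- which(keep) - 1L
  labels <- hypnogram$labels[keep]

  outliers <- vector("list", nrow(bands))
  names(outliers) <- band_labels(bands)
  if (!is.na(grubbs_alpha) && nrow(values) >= 3L) {
    for (b in seq_len(ncol(values))) {
      g <- grubbs_replace(values[, b], grubbs_alpha)
      values[, b] <- g$series
      outliers[[b]] <- g$outliers
    }
  }
  if (zscore && nrow(values) >= 2L) {
    values <- apply(values, 2L, remhf::zscore)
  }

  structure(
    list(values = values, epoch_index = epoch_index, labels = labels,
         bands = bands, channel = channel,
         dropped_epochs = which(!keep) - 1L,
         outliers = outliers, zscored = isTRUE(zscore),
         excised_intervals = exc$intervals,
         epoch_seconds = hypnogram$epoch_seconds,
         start_hour_of_day = hypnogram$start_hour_of_day,
         band_power_mode = band_power_mode),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d epochs x %d bands, channel %s%s\n",
    nrow(x$values), ncol(x$values), x$channel,
    if (x$zscored) " (z-scored)" else ""
  ))
  cat(sprintf("  dropped epochs: %d; outliers replaced: %d\n",
              length(x$dropped_epochs), sum(lengths(x$outliers))))
  invisible(x)
}

#' Hourly band power and state percentages
#'
#' Bins a recording into one-hour blocks (900 epochs at 4 s) and reports the
#' mean z-scored band power together with the percentage of WAKE and REM
#' epochs in each block; the table behind hourly power/state correlations.
#'
#' @param features a [extract_features()] result.
#' @param hypnogram the matching [hypnogram()] (state percentages are
#'   computed from all epochs, including any dropped from the features).
#' @return Data frame with one row per complete hour: `hour` (0-based),
#'   `hour_of_day`, `pct_wake`, `pct_rem`, and one mean-power column per
#'   band.
#' @export
hourly_summary <- function(features, hypnogram) {
  stopifnot(inherits(features, "feature_matrix"), inherits(hypnogram, "hypnogram"))
  per_hour <- round(3600 / hypnogram$epoch_seconds)
  n_hours <- length(hypnogram$labels) %/% per_hour
  if (n_hours < 1L) stop("need at least one full hour of epochs")
  hour_all <- (seq_along(hypnogram$labels) - 1L) %/% per_hour
  hour_feat <- features$epoch_index %/% per_hour
  out <- data.frame(
    hour = 0:(n_hours - 1L),
    hour_of_day = (hypnogram$start_hour_of_day + 0:(n_hours - 1L)) %% 24
  )
  lab <- hypnogram$labels[hour_all < n_hours]
  hh <- factor(hour_all[hour_all < n_hours], levels = 0:(n_hours - 1L))
  out$pct_wake <- as.numeric(100 * tapply(lab == "WAKE", hh, mean))
  out$pct_rem <- as.numeric(100 * tapply(lab == "REM", hh, mean))
  sel <- hour_feat < n_hours
  for (b in colnames(features$values)) {
    m <- tapply(features$values[sel, b], factor(hour_feat[sel], levels = 0:(n_hours - 1L)), mean)
    out[[b]] <- as.numeric(m)
  }
  rownames(out) <- NULL
  out
}
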