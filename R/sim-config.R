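#' Default per-state spectral gain table
#'
#' Amplitude gains (per state, per band) applied to band-limited noise in the
#' synthetic EEG. Defaults encode the qualitative spectral signature the
#' pipeline exploits: power above 80 Hz is highest in wakefulness,
#' intermediate in NREM and lowest in REM sleep, while the low bands are
#' shaped mainly by the delta/theta oscillation components.
#'
#' @param bands a band table (see [band_table()]).
#' @return Numeric matrix, rows `WAKE`/`NREM`/`REM`, one column per band.
#' @export
default_band_gains <- function(bands = band_table()) {
  nb <- nrow(bands)
  g <- matrix(1, nrow = 3L, ncol = nb,
              dimnames = list(vigilance_states(), band_labels(bands)))
  high <- bands$low_hz >= 80
  mid <- bands$low_hz >= 13 & !high
  g["NREM", mid] <- 0.75
  g["REM", mid] <- 0.75
  g["NREM", high] <- 0.55
  g["REM", high] <- 0.35
  g
}

#' Simulation configuration
#'
#' Parameters of the synthetic polysomnography generator. Defaults describe a
#' 23-h mouse recording started at light onset (09:00) under a 12/12-h
#' light/dark cycle, scored in 4-s epochs, with overall state budget of about
#' 47% wakefulness, 48% NREM and 5% REM sleep.
#'
#' The signal model per epoch is stationary Gaussian noise with one-sided
#' power spectral density
#' \deqn{S(f) = c^2 f^{-\beta} + \sum_b g^2_{s,b}\,1[f \in b] +
#'       a_\delta^2(s)\,1[f \in 1..4] + a_\theta^2(s)\,1[f \in 6..9]}
#' where \eqn{s} is the epoch's vigilance state, \eqn{g_{s,b}} the entries of
#' `band_gain_table`, and the delta/theta narrowband terms carry the classic
#' NREM delta and REM theta signatures. The EMG channel is white noise whose
#' per-epoch RMS encodes muscle tone (REM atonia < NREM < WAKE).
#'
#' @param sampling_rate_hz sampling rate (Hz); must exceed twice the highest
#'   analysis frequency (1000 Hz for bands reaching 500 Hz).
#' @param epoch_seconds scoring epoch length (s).
#' @param duration_hours recording duration (h).
#' @param start_hour_of_day clock hour of the first sample.
#' @param light_onset_hour,dark_onset_hour light-cycle switch points.
#' @param target_state_fractions named simplex over WAKE/NREM/REM: overall
#'   epoch budget the semi-Markov chain is calibrated to.
#' @param circadian_amplitude named relative modulation of the WAKE and REM
#'   targets between phases: WAKE is scaled up by its amplitude in the dark
#'   phase and down in the light phase; REM the other way around (nocturnal
#'   animal). NREM absorbs the residual.
#' @param state_dwell_means_epochs mean bout length per state, in epochs
#'   (geometric dwell law); all >= 1.
#' @param band_gain_table 3 x n_bands amplitude gain matrix, see
#'   [default_band_gains()].
#' @param oscillation_params list with `delta_band`, `theta_band` (Hz) and
#'   per-state amplitudes `delta_amp`, `theta_amp`.
#' @param one_over_f_exponent,one_over_f_scale background spectrum
#'   `scale^2 * f^-exponent`.
#' @param emg_rms_per_state EMG RMS (signal units) per state; must satisfy
#'   REM < NREM < WAKE.
#' @param artifact_rate_per_wake_epoch probability that a WAKE epoch carries
#'   a movement artifact.
#' @param artifact_amplitude artifact peak height as a multiple of the clean
#'   channel SD.
#' @param artifact_duration_ms range (min, max) of artifact durations.
#' @param notch_50hz emulate the acquisition hardware's 50-Hz notch by
#'   zeroing 48-52 Hz in the synthesis spectrum (off by default).
#' @param crossfade_ms raised-cosine crossfade between consecutive epochs.
#' @param channels channel names to synthesize.
#' @param seed integer seed; the entire simulation is a deterministic
#'   function of the configuration.
#' @return Object of class `sim_config` (validated list).
#' @export
sim_config <- function(sampling_rate_hz = 1000,
                       epoch_seconds = 4,
                       duration_hours = 23,
                       start_hour_of_day = 9,
                       light_onset_hour = 9,
                       dark_onset_hour = 21,
                       target_state_fractions = c(WAKE = 0.47, NREM = 0.48, REM = 0.05),
                       circadian_amplitude = c(WAKE = 0.30, NREM = 0, REM = 0.50),
                       state_dwell_means_epochs = c(WAKE = 60, NREM = 40, REM = 12),
                       band_gain_table = default_band_gains(),
                       oscillation_params = list(
                         delta_band = c(1, 4),
                         theta_band = c(6, 9),
                         delta_amp = c(WAKE = 0.5, NREM = 4, REM = 0.5),
                         theta_amp = c(WAKE = 1, NREM = 0.5, REM = 3)
                       ),
                       one_over_f_exponent = 1,
                       one_over_f_scale = 1,
                       emg_rms_per_state = c(WAKE = 8, NREM = 2, REM = 1),
                       artifact_rate_per_wake_epoch = 0.05,
                       artifact_amplitude = 10,
                       artifact_duration_ms = c(20, 100),
                       notch_50hz = FALSE,
                       crossfade_ms = 10,
                       channels = c("eeg_v1", "eeg_s1", "eeg_m1", "emg"),
                       seed = 1L) {
  st <- vigilance_states()
  cfg <- list(
    sampling_rate_hz = sampling_rate_hz,
    epoch_seconds = epoch_seconds,
    duration_hours = duration_hours,
    start_hour_of_day = start_hour_of_day,
    light_onset_hour = light_onset_hour,
    dark_onset_hour = dark_onset_hour,
    target_state_fractions = target_state_fractions[st],
    circadian_amplitude = circadian_amplitude[st],
    state_dwell_means_epochs = state_dwell_means_epochs[st],
    band_gain_table = band_gain_table,
    oscillation_params = oscillation_params,
    one_over_f_exponent = one_over_f_exponent,
    one_over_f_scale = one_over_f_scale,
    emg_rms_per_state = emg_rms_per_state[st],
    artifact_rate_per_wake_epoch = artifact_rate_per_wake_epoch,
    artifact_amplitude = artifact_amplitude,
    artifact_duration_ms = artifact_duration_ms,
    notch_50hz = isTRUE(notch_50hz),
    crossfade_ms = crossfade_ms,
    channels = channels,
    seed = as.integer(seed)
  )
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  st <- vigilance_states()
  f <- cfg$target_state_fractions
  if (anyNA(f) || any(f < 0)) stop("target_state_fractions must be named non-negative values for ", paste(st, collapse = "/"))
  if (abs(sum(f) - 1) > 1e-9) stop("target_state_fractions must sum to 1 (got ", format(sum(f)), ")")
  m <- cfg$state_dwell_means_epochs
  if (anyNA(m) || any(m < 1)) stop("state_dwell_means_epochs must all be >= 1")
  e <- cfg$emg_rms_per_state
  # non-strict so that fully silent degenerate configs (all-zero signals)
  # remain expressible; defaults are strictly ordered (REM atonia)
  if (anyNA(e) || any(e < 0) || !(e[["REM"]] <= e[["NREM"]] && e[["NREM"]] <= e[["WAKE"]])) {
    stop("emg_rms_per_state must satisfy REM <= NREM <= WAKE (muscle atonia)")
  }
  if (any(cfg$band_gain_table < 0)) stop("band gains must be non-negative")
  if (!identical(rownames(cfg$band_gain_table), st)) {
    stop("band_gain_table rows must be ", paste(st, collapse = ", "))
  }
  r <- cfg$artifact_rate_per_wake_epoch
  if (r < 0 || r > 1) stop("artifact_rate_per_wake_epoch must lie in [0, 1]")
  stopifnot(
    cfg$sampling_rate_hz > 0, cfg$epoch_seconds > 0, cfg$duration_hours > 0,
    cfg$one_over_f_scale >= 0, cfg$crossfade_ms >= 0,
    length(cfg$artifact_duration_ms) == 2L,
    cfg$artifact_duration_ms[1] <= cfg$artifact_duration_ms[2]
  )
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %g h @ %g Hz, %g-s epochs, seed %d\n",
    x$duration_hours, x$sampling_rate_hz, x$epoch_seconds, x$seed
  ))
  cat("  target fractions:",
      paste(sprintf("%s %.2f", names(x$target_state_fractions),
                    x$target_state_fractions), collapse = ", "), "\n")
  invisible(x)
}
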