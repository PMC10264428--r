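# Hour-of-day for each epoch and whether it falls in the dark phase.
epoch_hour_of_day <- function(n_epochs, epoch_seconds, start_hour_of_day) {
  (start_hour_of_day + floor((seq_len(n_epochs) - 1L) * epoch_seconds / 3600)) %% 24
}

is_dark_hour <- function(hour_of_day, light_onset, dark_onset) {
  # light phase = [light_onset, dark_onset), dark phase the complement
  if (light_onset < dark_onset) {
    !(hour_of_day >= light_onset & hour_of_day < dark_onset)
  } else {
    hour_of_day >= dark_onset & hour_of_day < light_onset
  }
}

# Phase-modulated state targets: WAKE scaled up in the dark, REM up in the
# light (nocturnal animal); NREM absorbs the residual probability mass.
modulated_fractions <- function(cfg, dark) {
  f <- cfg$target_state_fractions
  a <- cfg$circadian_amplitude
  m <- if (dark) 1 else -1
  fw <- f[["WAKE"]] * (1 + a[["WAKE"]] * m)
  fr <- f[["REM"]] * (1 - a[["REM"]] * m)
  fn <- 1 - fw - fr
  if (fn < 0) stop("circadian modulation pushes NREM fraction below 0")
  c(WAKE = fw, NREM = fn, REM = fr)
}

# Per-epoch Markov transition matrix with self-transitions fixed by the
# geometric dwell means (P_ss = 1 - 1/mean) and the embedded jump chain
# calibrated so the stationary law matches `target` exactly.
#
# Semi-Markov identity: the full-chain stationary probability of state i is
# proportional to nu_i * m_i, where nu is the stationary law of the jump
# chain and m_i the mean dwell. So the jump chain must have stationary
# nu ~ target / m. The family R_ij = w_j / (1 - w_i) (i != j, weights w on
# the simplex) has jump stationary ~ w_i (1 - w_i), leaving a scalar fixed
# point w = normalize(nu / (1 - w)) that converges for any interior target.
transition_matrix <- function(target, dwell_means) {
  st <- vigilance_states()
  target <- target / sum(target)
  active <- target > 1e-12
  if (sum(active) == 1L) {
    P <- diag(3); dimnames(P) <- list(st, st)
    return(P)
  }
  if (sum(active) == 2L) {
    # a two-state jump chain alternates, so the stationary law is set by the
    # dwell means alone; rescale the second dwell mean to honour the target
    ij <- which(active)
    P <- diag(3); dimnames(P) <- list(st, st)
    m1 <- dwell_means[ij[1L]]
    m2 <- max(1, m1 * target[ij[2L]] / target[ij[1L]])
    for (k in 1:2) {
      m <- c(m1, m2)[k]
      P[ij[k], ij[k]] <- 1 - 1 / m
      P[ij[k], ij[3L - k]] <- 1 / m
    }
    return(P)
  }
  leave <- target / dwell_means
  # no jump chain can give one state more than half of the jump-stationary
  # mass, i.e. one state's leave rate cannot exceed the other two combined;
  # if the configured dwell means violate that for this target, lengthen the
  # offending state's bouts just enough (bout lengths do vary with circadian
  # phase, so this is the biologically sensible degree of freedom to bend)
  for (j in 1:3) {
    other <- sum(leave[-j])
    if (leave[j] > 0.96 * other) leave[j] <- 0.96 * other
  }
  dwell_means <- target / leave
  nu <- leave / sum(leave)
  w <- nu
  for (iter in 1:5000) {
    w_new <- nu / pmax(1 - w, 1e-12)
    w_new <- w_new / sum(w_new)
    if (max(abs(w_new - w)) < 1e-14) { w <- w_new; break }
    w <- w_new
  }
  resid <- w * (1 - w) / sum(w * (1 - w)) - nu
  if (max(abs(resid)) > 1e-8) {
    stop("cannot calibrate jump chain for target fractions ",
         paste(sprintf("%.3f", target), collapse = ", "))
  }
  P <- matrix(0, 3, 3, dimnames = list(st, st))
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) P[i, j] <- (1 / dwell_means[i]) * w[j] / (1 - w[i])
    }
    P[i, i] <- 1 - sum(P[i, -i])
  }
  P
}

#' Simulate a hypnogram
#'
#' Draws a vigilance-state sequence from a semi-Markov chain with geometric
#' dwell times and hour-of-day-dependent transition probabilities: the chain
#' is re-calibrated for the light and dark phases so that wakefulness
#' dominates the dark phase and REM sleep is enriched in the light phase,
#' while the overall state budget approximates `target_state_fractions`.
#'
#' @param config a [sim_config()].
#' @return A [hypnogram()] with one label per epoch; deterministic in
#'   `config$seed`.
#' @export
simulate_hypnogram <- function(config) {
  config <- validate_sim_config(config)
  st <- vigilance_states()
  n_epochs <- floor(config$duration_hours * 3600 / config$epoch_seconds)
  if (n_epochs < 1L) stop("duration shorter than one epoch")
  hod <- epoch_hour_of_day(n_epochs, config$epoch_seconds, config$start_hour_of_day)
  dark <- is_dark_hour(hod, config$light_onset_hour, config$dark_onset_hour)

  # degenerate chain: one state takes all probability mass
  f <- config$target_state_fractions
  if (any(f >= 1 - 1e-12)) {
    lab <- st[which.max(f)]
    return(hypnogram(rep(lab, n_epochs), config$epoch_seconds,
                     config$start_hour_of_day))
  }

  P_light <- transition_matrix(modulated_fractions(config, dark = FALSE),
                               config$state_dwell_means_epochs)
  P_dark <- transition_matrix(modulated_fractions(config, dark = TRUE),
                              config$state_dwell_means_epochs)

  set.seed(config$seed)
  labels <- integer(n_epochs)
  f0 <- modulated_fractions(config, dark = dark[1L])
  labels[1L] <- sample.int(3L, 1L, prob = f0)
  u <- stats::runif(n_epochs)
  cum_light <- apply(P_light, 1L, cumsum)  # 3 x 3, column = current state
  cum_dark <- apply(P_dark, 1L, cumsum)
  for (t in 2:n_epochs) {
    cum <- if (dark[t]) cum_dark else cum_light
    labels[t] <- findInterval(u[t], cum[, labels[t - 1L]]) + 1L
  }
  hypnogram(st[labels], config$epoch_seconds, config$start_hour_of_day)
}

# One-sided PSD target (per state) on the synthesis frequency grid.
state_psd <- function(config, state, freqs) {
  S <- rep(0, length(freqs))
  pos <- freqs > 0
  S[pos] <- config$one_over_f_scale^2 * freqs[pos]^(-config$one_over_f_exponent)
  bands <- band_table()
  gains <- config$band_gain_table[state, ]
  stopifnot(length(gains) == nrow(bands))
  for (b in seq_len(nrow(bands))) {
    sel <- freqs >= bands$low_hz[b] & freqs < bands$high_hz[b]
    S[sel] <- S[sel] + gains[b]^2
  }
  op <- config$oscillation_params
  sel <- freqs >= op$delta_band[1] & freqs < op$delta_band[2]
  S[sel] <- S[sel] + op$delta_amp[[state]]^2
  sel <- freqs >= op$theta_band[1] & freqs < op$theta_band[2]
  S[sel] <- S[sel] + op$theta_amp[[state]]^2
  if (config$notch_50hz) S[freqs >= 48 & freqs < 52] <- 0
  S[freqs > config$sampling_rate_hz / 2] <- 0
  S
}

# Synthesize `n` samples of stationary Gaussian noise with one-sided PSD
# amplitude `amp` (precomputed by noise_spectrum()) by inverse-FFT of a
# randomly-phased spectrum. The synthesis length is a power of two for FFT
# speed and the surplus discarded; a window of a stationary process is still
# the same process.
noise_spectrum <- function(n, fs, psd_fun) {
  L <- 2^ceiling(log2(max(n, 2L)))
  half <- L %/% 2L
  freqs <- (0:half) * fs / L
  list(L = L, half = half, amp = sqrt(psd_fun(freqs) * L * fs / 2))
}

synth_colored_noise <- function(n, spec) {
  half <- spec$half
  re <- stats::rnorm(half + 1L)
  im <- stats::rnorm(half + 1L)
  X <- complex(real = spec$amp * re, imaginary = spec$amp * im) / sqrt(2)
  X[1L] <- 0                                        # zero mean
  X[half + 1L] <- spec$amp[half + 1L] * re[half + 1L]  # Nyquist bin real
  full <- c(X, Conj(X[half:2]))
  x <- Re(stats::fft(full, inverse = TRUE)) / spec$L
  x[seq_len(n)]
}

#' Synthesize EEG/EMG signals for a hypnogram
#'
#' For every epoch, draws stationary Gaussian noise whose power spectral
#' density follows the state-conditional model in [sim_config()] (1/f
#' background, per-band gains, delta and theta narrowband components), and
#' stitches consecutive epochs with a short raised-cosine crossfade to avoid
#' broadband leakage from boundary steps. EEG channels are independent
#' realizations of the same state-conditional spectrum; the EMG channel is
#' white noise with state-dependent RMS (REM atonia).
#'
#' @param hypnogram a [hypnogram()].
#' @param config a [sim_config()]; epoch length must match the hypnogram.
#' @param channels channels to synthesize (default `config$channels`); use a
#'   subset (e.g. `c("eeg_v1", "emg")`) to bound memory on long recordings.
#' @return A [recording()]; deterministic in `config$seed`.
#' @export
simulate_signals <- function(hypnogram, config, channels = config$channels) {
  config <- validate_sim_config(config)
  stopifnot(inherits(hypnogram, "hypnogram"))
  if (abs(hypnogram$epoch_seconds - config$epoch_seconds) > 1e-9) {
    stop("hypnogram epoch length (", hypnogram$epoch_seconds,
         " s) does not match config (", config$epoch_seconds, " s)")
  }
  if (!all(hypnogram$labels %in% vigilance_states())) {
    stop("hypnogram contains unknown state labels")
  }
  fs <- config$sampling_rate_hz
  N <- round(fs * config$epoch_seconds)
  w <- round(config$crossfade_ms / 1000 * fs)
  n_epochs <- length(hypnogram$labels)
  n_total <- n_epochs * N
  up <- if (w > 0) 0.5 * (1 - cos(pi * seq_len(w) / (w + 1))) else numeric(0)

  specs <- lapply(stats::setNames(nm = vigilance_states()), function(s) {
    noise_spectrum(N + w, fs, function(f) state_psd(config, s, f))
  })

  set.seed(config$seed + 1L)
  out <- vector("list", length(channels))
  names(out) <- channels
  for (ch in channels) {
    is_emg <- grepl("emg", ch, ignore.case = TRUE)
    sig <- numeric(n_total + w)
    for (i in seq_len(n_epochs)) {
      stt <- hypnogram$labels[i]
      if (is_emg) {
        seg <- stats::rnorm(N + w) * config$emg_rms_per_state[[stt]]
      } else {
        seg <- synth_colored_noise(N + w, specs[[stt]])
      }
      if (w > 0) {
        if (i > 1L) seg[seq_len(w)] <- seg[seq_len(w)] * up
        seg[N + seq_len(w)] <- seg[N + seq_len(w)] * (1 - up)
      }
      idx <- (i - 1L) * N
      sig[(idx + 1L):(idx + N + w)] <- sig[(idx + 1L):(idx + N + w)] + seg
    }
    out[[ch]] <- sig[seq_len(n_total)]
  }
  recording(out, fs, start_hour_of_day = hypnogram$start_hour_of_day)
}

#' Inject movement artifacts into WAKE epochs
#'
#' Adds, with probability `artifact_rate_per_wake_epoch` per WAKE epoch, a
#' high-amplitude raised-cosine transient (peak `artifact_amplitude` times
#' the clean channel SD, duration drawn from `artifact_duration_ms`) to all
#' EEG channels simultaneously, emulating the movement artifacts that the
#' feature-extraction stage must excise. Ground-truth event times are
#' returned so the excision stage can be validated.
#'
#' @param recording a [recording()].
#' @param hypnogram the matching [hypnogram()].
#' @param config a [sim_config()].
#' @return List with `recording` (modified copy) and `artifacts`, a data
#'   frame with `epoch_index` (0-based), `onset_s`, `duration_s`,
#'   `peak_amplitude`.
#' @export
inject_artifacts <- function(recording, hypnogram, config) {
  config <- validate_sim_config(config)
  stopifnot(inherits(recording, "recording"), inherits(hypnogram, "hypnogram"))
  fs <- recording$sampling_rate_hz
  N <- round(fs * hypnogram$epoch_seconds)
  rate <- config$artifact_rate_per_wake_epoch
  eeg_chs <- names(recording$channel_roles)[recording$channel_roles == "eeg"]
  empty <- data.frame(epoch_index = integer(0), onset_s = numeric(0),
                      duration_s = numeric(0), peak_amplitude = numeric(0))
  if (rate == 0 || length(eeg_chs) == 0L) {
    return(list(recording = recording, artifacts = empty))
  }
  set.seed(config$seed + 2L)
  wake <- which(hypnogram$labels == "WAKE")
  hit <- wake[stats::runif(length(wake)) < rate]
  if (length(hit) == 0L) return(list(recording = recording, artifacts = empty))

  dur_s <- stats::runif(length(hit), config$artifact_duration_ms[1],
                        config$artifact_duration_ms[2]) / 1000
  # keep the transient inside its epoch, away from the crossfaded edges
  rel <- stats::runif(length(hit), 0.05, 0.95 - dur_s / hypnogram$epoch_seconds)
  onset_s <- (hit - 1L) * hypnogram$epoch_seconds + rel * hypnogram$epoch_seconds
  sds <- vapply(recording$channels[eeg_chs], stats::sd, numeric(1))
  for (k in seq_along(hit)) {
    n_art <- max(2L, round(dur_s[k] * fs))
    bump <- 0.5 * (1 - cos(2 * pi * seq_len(n_art) / (n_art + 1)))
    i0 <- round(onset_s[k] * fs)
    for (ch in eeg_chs) {
      amp <- config$artifact_amplitude * sds[[ch]]
      idx <- i0 + seq_len(n_art)
      recording$channels[[ch]][idx] <- recording$channels[[ch]][idx] + amp * bump
    }
  }
  list(
    recording = recording,
    artifacts = data.frame(
      epoch_index = hit - 1L, onset_s = onset_s, duration_s = dur_s,
      peak_amplitude = config$artifact_amplitude * max(sds)
    )
  )
}
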