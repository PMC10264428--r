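#' Vigilance state vocabulary
#'
#' The three vigilance states scored on rodent polysomnography: wakefulness
#' (`WAKE`), non-REM sleep (`NREM`) and REM sleep (`REM`). All hypnogram
#' labels in the package are drawn from this vocabulary.
#'
#' @return Character vector `c("WAKE", "NREM", "REM")`.
#' @export
vigilance_states <- function() c("WAKE", "NREM", "REM")

# Common label spellings found in scoring exports, mapped onto the canonical
# three-state vocabulary.
.state_aliases <- c(
  WAKE = "WAKE", W = "WAKE", WAKEFULNESS = "WAKE", AWAKE = "WAKE",
  NREM = "NREM", NREMS = "NREM", NR = "NREM", SWS = "NREM", N = "NREM",
  REM = "REM", REMS = "REM", R = "REM", PS = "REM"
)

#' Normalise vigilance-state labels
#'
#' Maps common aliases (`"REMS"`, `"NREMS"`, `"W"`, ...) onto the canonical
#' `WAKE`/`NREM`/`REM` vocabulary, case-insensitively.
#'
#' @param x character vector of labels.
#' @return Character vector of canonical states.
#' @export
normalize_states <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- .state_aliases[key]
  if (anyNA(out)) {
    bad <- which(is.na(out))[1L]
    stop("unknown vigilance state label '", x[bad], "' at position ", bad)
  }
  unname(out)
}

#' Construct a hypnogram
#'
#' A hypnogram is the sequence of vigilance-state labels over a recording,
#' one label per fixed-length scoring epoch (4 s by default).
#'
#' @param labels character vector of states (aliases accepted).
#' @param epoch_seconds epoch length in seconds.
#' @param start_hour_of_day clock hour at which epoch 0 starts (recordings
#'   conventionally begin at 09:00, the light onset).
#' @return An object of class `hypnogram`: list with `labels`,
#'   `epoch_seconds`, `start_hour_of_day`.
#' @export
hypnogram <- function(labels, epoch_seconds = 4, start_hour_of_day = 9) {
  if (length(labels) == 0L) stop("hypnogram must contain at least one epoch")
  stopifnot(epoch_seconds > 0)
  structure(
    list(
      labels = normalize_states(labels),
      epoch_seconds = epoch_seconds,
      start_hour_of_day = start_hour_of_day
    ),
    class = "hypnogram"
  )
}

#' @export
length.hypnogram <- function(x) length(x$labels)

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = vigilance_states()))
  cat(sprintf(
    "<hypnogram> %d epochs of %gs (%.2f h), starting %02d:00\n",
    length(x$labels), x$epoch_seconds,
    length(x$labels) * x$epoch_seconds / 3600, x$start_hour_of_day
  ))
  frac <- prop.table(tab)
  for (s in names(tab)) {
    cat(sprintf("  %-5s %6d epochs (%5.1f%%)\n", s, tab[[s]], 100 * frac[[s]]))
  }
  invisible(x)
}

#' State fractions of a hypnogram
#'
#' @param hyp a [hypnogram()].
#' @return Named numeric vector of epoch fractions over WAKE/NREM/REM.
#' @export
state_fractions <- function(hyp) {
  stopifnot(inherits(hyp, "hypnogram"))
  tab <- table(factor(hyp$labels, levels = vigilance_states()))
  stats::setNames(as.numeric(tab) / length(hyp$labels), vigilance_states())
}

#' Construct a multichannel recording
#'
#' Container for continuous polysomnography signals: named channels sampled
#' at a common rate, with channel roles distinguishing EEG derivations
#' (epidural V1/S1/M1 screws) from the nuchal EMG.
#'
#' @param channels named list of equal-length numeric vectors.
#' @param sampling_rate_hz sampling rate in Hz (>= 1000 for analysis of
#'   bands reaching 500 Hz).
#' @param channel_roles named character vector mapping channel name to role
#'   `"eeg"` or `"emg"`; guessed from names when omitted.
#' @param start_hour_of_day clock hour of the first sample.
#' @return An object of class `recording`.
#' @export
recording <- function(channels, sampling_rate_hz,
                      channel_roles = NULL, start_hour_of_day = 9) {
  stopifnot(is.list(channels), length(channels) >= 1L, sampling_rate_hz > 0)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    stop("all channels must be named")
  }
  n <- unique(vapply(channels, length, integer(1)))
  if (length(n) != 1L) stop("all channels must have equal length")
  if (is.null(channel_roles)) {
    channel_roles <- ifelse(grepl("emg", names(channels), ignore.case = TRUE),
                            "emg", "eeg")
    names(channel_roles) <- names(channels)
  }
  structure(
    list(
      channels = channels,
      sampling_rate_hz = sampling_rate_hz,
      channel_roles = channel_roles,
      start_hour_of_day = start_hour_of_day
    ),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$channels[[1L]])
  cat(sprintf(
    "<recording> %d channel(s), %d samples @ %g Hz (%.2f h)\n",
    length(x$channels), n, x$sampling_rate_hz,
    n / x$sampling_rate_hz / 3600
  ))
  for (ch in names(x$channels)) {
    cat(sprintf("  %-8s [%s]\n", ch, x$channel_roles[[ch]]))
  }
  invisible(x)
}

# Return the names of channels with a given role, erroring helpfully when the
# role is absent (e.g. scoring a recording that has no EMG channel).
channels_with_role <- function(rec, role) {
  stopifnot(inherits(rec, "recording"))
  hits <- names(rec$channel_roles)[rec$channel_roles == role]
  if (length(hits) == 0L) {
    stop("recording has no channel with role '", role, "' (channels: ",
         paste(names(rec$channels), collapse = ", "), ")")
  }
  hits
}
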