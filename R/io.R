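# fixed-width ASCII field for EDF headers
edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)  # left-justified, space padded
}

#' Write a recording to EDF
#'
#' European Data Format: 16-bit integers with per-channel physical scaling,
#' 1-s data records. The portable interchange format for polysomnography;
#' physical units are microvolts. The signal is truncated to a whole number
#' of records (at 1-s records and integer-second durations, nothing is
#' lost). Quantization error is bounded by one step of the physical/digital
#' range mapping.
#'
#' @param recording a [recording()].
#' @param path output file.
#' @param start_date date string `dd.mm.yy` stored in the header (a fixed
#'   default keeps files byte-reproducible).
#' @return Invisibly, `path`.
#' @export
write_edf <- function(recording, path, start_date = "01.01.01") {
  stopifnot(inherits(recording, "recording"))
  fs <- recording$sampling_rate_hz
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export requires an integer sampling rate")
  fs <- as.integer(round(fs))
  chans <- recording$channels
  ns <- length(chans)
  n <- length(chans[[1L]])
  n_rec <- n %/% fs
  if (n_rec < 1L) stop("recording shorter than one 1-s EDF record")

  pm <- vapply(chans, function(x) max(abs(range(x)), 1e-6), numeric(1))
  dmin <- -32768; dmax <- 32767
  start_time <- sprintf("%02d.00.00", round(recording$start_hour_of_day) %% 24)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field("synthetic mouse", 80),
    edf_field("remhf simulated polysomnography", 80),
    edf_field(start_date, 8),
    edf_field(start_time, 8),
    edf_field(256 * (ns + 1L), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_field, character(1), width = width),
                     collapse = ""), con, eos = NULL)
  }
  roles <- toupper(recording$channel_roles[names(chans)])
  per_sig(paste(roles, names(chans)), 16)            # label: "EEG eeg_v1"
  per_sig(rep("simulated", ns), 80)                  # transducer
  per_sig(rep("uV", ns), 8)                          # physical dimension
  per_sig(sprintf("%.6g", -pm), 8)
  per_sig(sprintf("%.6g", pm), 8)
  per_sig(rep(dmin, ns), 8)
  per_sig(rep(dmax, ns), 8)
  per_sig(rep("", ns), 80)                           # prefilter
  per_sig(rep(fs, ns), 8)                            # samples per record
  per_sig(rep("", ns), 32)                           # reserved

  # digital conversion per channel, then interleave records
  dig <- lapply(seq_along(chans), function(i) {
    x <- chans[[i]][seq_len(n_rec * fs)]
    d <- round((x + pm[i]) / (2 * pm[i]) * (dmax - dmin) + dmin)
    as.integer(pmin(pmax(d, dmin), dmax))
  })
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads a (continuous, equal-rate) EDF file written by [write_edf()] or any
#' other EDF writer with a common sampling rate across channels.
#'
#' @param path EDF file.
#' @return A [recording()]; channel roles are recovered from the EEG/EMG
#'   prefix of the signal labels.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                       # version
  rd(80); rd(80)              # patient, recording id
  rd(8)                       # start date
  start_time <- rd(8)
  rd(8)                       # header bytes
  rd(44)                      # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # dimension
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)          # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)          # reserved
  if (length(unique(spr / rec_dur)) != 1L) {
    stop("mixed sampling rates across channels are not supported")
  }
  total <- sum(spr)
  raw <- readBin(con, "integer", n = n_rec * total, size = 2L,
                 endian = "little", signed = TRUE)
  chans <- vector("list", ns)
  offs <- c(0L, cumsum(spr))
  for (i in seq_len(ns)) {
    idx <- as.vector(outer(offs[i] + seq_len(spr[i]), (0:(n_rec - 1L)) * total, "+"))
    d <- raw[idx]
    chans[[i]] <- (d - dmin_[i]) / (dmax_[i] - dmin_[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  name_of <- sub("^(EEG|EMG)\\s+", "", labels, ignore.case = TRUE)
  roles <- ifelse(grepl("^EMG", labels, ignore.case = TRUE) |
                    grepl("emg", name_of, ignore.case = TRUE), "emg", "eeg")
  names(chans) <- name_of
  names(roles) <- name_of
  hh <- suppressWarnings(as.integer(substr(start_time, 1L, 2L)))
  recording(chans, spr[1L] / rec_dur, channel_roles = roles,
            start_hour_of_day = if (is.na(hh)) 0L else hh)
}

#' Hypnogram CSV I/O
#'
#' The on-disk hypnogram dialect: a CSV with header
#' `epoch_index,start_time_s,state`, epoch indices 0-based and contiguous.
#' Reading accepts common state aliases (`REMS`, `NREMS`, `W`, ...) and
#' errors, citing the row, on unknown labels or index gaps.
#'
#' @param hypnogram a [hypnogram()].
#' @param path CSV path.
#' @param epoch_seconds,start_hour_of_day bookkeeping used when reading.
#' @return `write_hypnogram` invisibly returns `path`; `read_hypnogram`
#'   returns a [hypnogram()].
#' @export
write_hypnogram <- function(hypnogram, path) {
  stopifnot(inherits(hypnogram, "hypnogram"))
  df <- data.frame(
    epoch_index = seq_along(hypnogram$labels) - 1L,
    start_time_s = (seq_along(hypnogram$labels) - 1L) * hypnogram$epoch_seconds,
    state = hypnogram$labels
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path, epoch_seconds = NULL, start_hour_of_day = 9) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "start_time_s", "state")
  if (!all(need %in% colnames(df))) {
    stop("hypnogram CSV must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty hypnogram file")
  expected <- 0:(nrow(df) - 1L)
  if (!identical(as.integer(df$epoch_index), expected)) {
    bad <- which(as.integer(df$epoch_index) != expected)[1L]
    stop("epoch_index must be contiguous from 0; first problem at data row ", bad)
  }
  states <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(normalize_states(df$state[i]),
             error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
  }, character(1))
  if (is.null(epoch_seconds)) {
    epoch_seconds <- if (nrow(df) >= 2L) df$start_time_s[2L] - df$start_time_s[1L] else 4
  }
  hypnogram(states, epoch_seconds, start_hour_of_day)
}

#' Feature table CSV I/O
#'
#' Flat export of a [extract_features()] result: `epoch_index`, `state`,
#' `channel`, then one column per band (band labels have `Hz` stripped to
#' `X0.1.4Hz`-safe names on read).
#'
#' @param features a `feature_matrix`.
#' @param path CSV path.
#' @return `write_features` invisibly returns `path`; `read_features`
#'   returns a list with `values`, `labels`, `epoch_index`, `channel`.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_matrix"))
  df <- data.frame(epoch_index = features$epoch_index,
                   state = features$labels,
                   channel = features$channel,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(features$values, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("epoch_index", "state", "channel")
  if (!all(need %in% colnames(df))) {
    stop("feature CSV must have columns ", paste(need, collapse = ", "))
  }
  vals <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  list(values = vals, labels = normalize_states(df$state),
       epoch_index = as.integer(df$epoch_index),
       channel = df$channel[1L])
}

#' Raw float32 + JSON-header recording I/O
#'
#' Lossless fallback interchange format: little-endian float32 samples,
#' channels concatenated, with a JSON sidecar (`<path>.json`) holding
#' channel names, roles, sampling rate and start hour. Float32 is exact for
#' test fixtures and avoids EDF's 16-bit quantization.
#'
#' @param recording a [recording()].
#' @param path binary output path.
#' @return `write_recording_raw` invisibly returns `path`;
#'   `read_recording_raw` returns a [recording()].
#' @export
write_recording_raw <- function(recording, path) {
  stopifnot(inherits(recording, "recording"))
  meta <- list(
    channels = names(recording$channels),
    roles = as.list(recording$channel_roles),
    sampling_rate_hz = recording$sampling_rate_hz,
    start_hour_of_day = recording$start_hour_of_day,
    n_samples = length(recording$channels[[1L]])
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  for (ch in names(recording$channels)) {
    writeBin(recording$channels[[ch]], con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_recording_raw
#' @export
read_recording_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  chans <- list()
  for (ch in meta$channels) {
    chans[[ch]] <- readBin(con, "numeric", n = meta$n_samples, size = 4L,
                           endian = "little")
  }
  roles <- unlist(meta$roles)
  recording(chans, meta$sampling_rate_hz, channel_roles = roles[meta$channels],
            start_hour_of_day = meta$start_hour_of_day)
}
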