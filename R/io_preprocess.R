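#' @title Recording I/O, filtering, channel selection, epoching
#' @name io_preprocess
NULL

#' The 10 channels used for anxiety detection
#'
#' Frontal and parietal subset of the EPOC montage retained for feature
#' extraction.
#' @export
ANXIETY_CHANNELS <- c("AF3", "F7", "F3", "F4", "F8", "AF4", "FC6", "FC5", "P7", "P8")

#' Construct an EEG recording
#'
#' @param signal channels x samples numeric matrix.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names ordered channel names, one per signal row.
#' @param subject_id,trial_id provenance identifiers.
#' @return an `eeg_recording` object.
#' @export
eeg_recording <- function(signal, sampling_rate, channel_names,
                          subject_id = NA, trial_id = NA) {
  signal <- as.matrix(signal)
  if (length(channel_names) != nrow(signal))
    stop("channel_names must have one entry per signal row", call. = FALSE)
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (!all(is.finite(signal)))
    stop("signal contains non-finite samples", call. = FALSE)
  rownames(signal) <- channel_names
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 channel_names = as.character(channel_names),
                 subject_id = subject_id, trial_id = trial_id),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (subject %s, trial %s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              as.character(x$subject_id), as.character(x$trial_id)))
  invisible(x)
}

#' Write a recording to CSV (one row per channel, first column = channel name)
#'
#' @param recording an `eeg_recording`.
#' @param path output file path.
#' @export
write_recording_csv <- function(recording, path) {
  df <- data.frame(channel = recording$channel_names,
                   recording$signal, check.names = FALSE)
  colnames(df) <- c("channel", paste0("s", seq_len(ncol(recording$signal))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path file path.
#' @param format `"csv"` (headered, first column = channel name, one row per
#'   channel) or `"edf"` (European Data Format, 16-bit).
#' @param sampling_rate sampling rate in Hz; required for CSV (the dialect does
#'   not carry it), ignored for EDF (taken from the header).
#' @param subject_id,trial_id provenance identifiers attached to the result.
#' @return an `eeg_recording`.
#' @export
read_recording <- function(path, format = c("csv", "edf"), sampling_rate = 128,
                           subject_id = NA, trial_id = NA) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("input file not found: %s", path), call. = FALSE)
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                   error = function(e)
                     stop(sprintf("cannot parse CSV %s: %s", path, conditionMessage(e)),
                          call. = FALSE))
    if (!"channel" %in% colnames(df))
      stop(sprintf("missing 'channel' header column in %s", path), call. = FALSE)
    sig <- as.matrix(df[, setdiff(colnames(df), "channel"), drop = FALSE])
    storage.mode(sig) <- "double"
    if (!all(is.finite(sig)))
      stop(sprintf("non-finite samples in %s", path), call. = FALSE)
    eeg_recording(sig, sampling_rate, df$channel,
                  subject_id = subject_id, trial_id = trial_id)
  } else {
    rec <- read_edf(path)
    eeg_recording(rec$signal, rec$sampling_rate, rec$channel_names,
                  subject_id = subject_id, trial_id = trial_id)
  }
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The default
#' 4-45 Hz band removes slow drifts and line-frequency content while keeping
#' theta through low gamma.
#'
#' @param recording an `eeg_recording`.
#' @param low,high corner frequencies in Hz.
#' @return the filtered `eeg_recording` (same length; no phase shift).
#' @export
bandpass <- function(recording, low = 4, high = 45) {
  nyq <- recording$sampling_rate / 2
  if (!(low > 0 && low < high && high < nyq))
    stop(sprintf("invalid band corners: need 0 < low < high < Nyquist (%g Hz)", nyq),
         call. = FALSE)
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  filt <- t(apply(recording$signal, 1, function(x)
    signal::filtfilt(bf, x)))
  recording$signal <- filt
  rownames(recording$signal) <- recording$channel_names
  recording
}

#' Restrict a recording to a channel subset
#'
#' @param recording an `eeg_recording`.
#' @param keep channel names to retain, in the order wanted; defaults to the
#'   10-channel anxiety montage.
#' @return the restricted `eeg_recording`.
#' @export
select_channels <- function(recording, keep = ANXIETY_CHANNELS) {
  missing <- setdiff(keep, recording$channel_names)
  if (length(missing))
    stop(sprintf("channels not in montage: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  recording$signal <- recording$signal[keep, , drop = FALSE]
  recording$channel_names <- keep
  recording
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive non-overlapping windows; a trailing partial window is discarded.
#'
#' @param recording an `eeg_recording`.
#' @param duration epoch length in seconds (default 1).
#' @return list of `eeg_epoch` objects (`epoch_index` is 0-based).
#' @export
epoch_recording <- function(recording, duration = 1) {
  if (duration <= 0) stop("epoch duration must be > 0", call. = FALSE)
  len <- round(duration * recording$sampling_rate)
  n <- ncol(recording$signal)
  if (n < len) stop("recording shorter than one epoch", call. = FALSE)
  n_ep <- n %/% len
  lapply(seq_len(n_ep) - 1L, function(i) {
    seg <- recording$signal[, (i * len + 1):((i + 1) * len), drop = FALSE]
    structure(list(signal = seg, sampling_rate = recording$sampling_rate,
                   channel_names = recording$channel_names,
                   subject_id = recording$subject_id,
                   trial_id = recording$trial_id, epoch_index = i),
              class = "eeg_epoch")
  })
}

#' Preprocess a list of recordings into epochs
#'
#' Band-pass, channel selection and epoching applied in sequence. A warning is
#' issued for rates other than 128 Hz since the wavelet band map assumes 128 Hz.
#'
#' @param recordings list of `eeg_recording`.
#' @param low,high band-pass corners in Hz.
#' @param keep channel subset.
#' @param duration epoch length in seconds.
#' @return flat list of `eeg_epoch`.
#' @export
preprocess <- function(recordings, low = 4, high = 45,
                       keep = ANXIETY_CHANNELS, duration = 1) {
  rates <- unique(vapply(recordings, `[[`, numeric(1), "sampling_rate"))
  if (any(rates != 128))
    warning("sampling rate is not 128 Hz; wavelet band edges will shift")
  unlist(lapply(recordings, function(r)
    epoch_recording(select_channels(bandpass(r, low, high), keep), duration)),
    recursive = FALSE)
}
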