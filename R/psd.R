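#' @title Power spectral density features
#' @description Single-segment Hann-window periodogram per 1-s epoch (128
#'   samples is too short for multi-segment Welch averaging), with band powers
#'   integrated over the canonical theta/alpha/beta/gamma ranges.
#' @name features_psd
NULL

PSD_BANDS <- data.frame(band = c("theta", "alpha", "beta", "gamma"),
                        low = c(4, 8, 13, 30), high = c(8, 13, 30, 40))

#' One-sided Hann periodogram of a single channel
#'
#' Density scaling makes the integral of the spectrum (rectangle rule at
#' resolution `sampling_rate / n`) equal the windowed power estimate, so for
#' white noise the total integrated power matches the time-domain variance in
#' expectation.
#'
#' @param x numeric vector (>= 64 samples).
#' @param sampling_rate sampling rate in Hz.
#' @return list with `frequencies` (Hz) and `density` ((signal units)^2 / Hz).
#' @export
psd_estimate <- function(x, sampling_rate) {
  n <- length(x)
  if (n < 64) stop("need at least 64 samples for a spectrum", call. = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)  # periodic Hann
  X <- stats::fft(x * w)
  n_keep <- n %/% 2 + 1
  dens <- Mod(X[seq_len(n_keep)])^2 / (sampling_rate * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when n is even)
  scale <- rep(2, n_keep)
  scale[1] <- 1
  if (n %% 2 == 0) scale[n_keep] <- 1
  list(frequencies = (seq_len(n_keep) - 1) * sampling_rate / n,
       density = dens * scale)
}

#' Integrated power of a frequency band
#'
#' Rectangle-rule integral of the density over bins with `low <= f < high`
#' (half-open, so adjacent bands never double-count an edge bin).
#'
#' @param spectrum a list from [psd_estimate()].
#' @param low,high band edges in Hz.
#' @return band power in (signal units)^2.
#' @export
band_power <- function(spectrum, low, high) {
  if (!(low >= 0 && low < high))
    stop("invalid band: need 0 <= low < high", call. = FALSE)
  df <- spectrum$frequencies[2] - spectrum$frequencies[1]
  sel <- spectrum$frequencies >= low & spectrum$frequencies < high
  sum(spectrum$density[sel]) * df
}

# per-channel band powers plus average/total, as a channels x 6 matrix
psd_band_powers <- function(epoch) {
  out <- t(vapply(epoch$channel_names, function(ch) {
    sp <- psd_estimate(epoch$signal[ch, ], epoch$sampling_rate)
    bp <- mapply(function(lo, hi) band_power(sp, lo, hi),
                 PSD_BANDS$low, PSD_BANDS$high)
    total <- sum(sp$density) * (sp$frequencies[2] - sp$frequencies[1])
    c(bp, mean(bp), total)
  }, numeric(6)))
  colnames(out) <- c(PSD_BANDS$band, "average_power", "total_power")
  out
}

#' Spectral feature block for one epoch
#'
#' Per channel: theta, alpha, beta and gamma band powers, their mean
#' (`average_power`) and the integral over the full one-sided spectrum
#' (`total_power`), stacked in montage order — 60 features for the 10-channel
#' montage. With `stack_bins = TRUE` the raw per-bin densities are appended as
#' well.
#'
#' @param epoch an `eeg_epoch` with 10 channels.
#' @param stack_bins also stack the raw per-bin spectrum of every channel?
#' @return named numeric vector (60 features by default).
#' @export
extract_psd_features <- function(epoch, stack_bins = FALSE) {
  if (nrow(epoch$signal) != length(ANXIETY_CHANNELS))
    stop(sprintf("expected %d channels, got %d",
                 length(ANXIETY_CHANNELS), nrow(epoch$signal)), call. = FALSE)
  bp <- psd_band_powers(epoch)
  vals <- as.vector(t(bp))
  names(vals) <- as.vector(vapply(rownames(bp), function(ch)
    paste(ch, colnames(bp), sep = "_"), character(ncol(bp))))
  if (stack_bins) {
    bins <- unlist(lapply(epoch$channel_names, function(ch) {
      sp <- psd_estimate(epoch$signal[ch, ], epoch$sampling_rate)
      stats::setNames(sp$density,
                      sprintf("%s_bin_%.1fHz", ch, sp$frequencies))
    }))
    vals <- c(vals, bins)
  }
  vals
}
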