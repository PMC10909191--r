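#' @title Daubechies-4 wavelet decomposition and statistical features
#' @description A dyadic filter-bank DWT with symmetric signal extension.
#'   Filter taps are the standard db4 analysis/synthesis quadruple; coefficient
#'   array lengths follow floor((n + filter_length - 1) / 2) per level, the
#'   convention of the common wavelet toolboxes, so decompositions are directly
#'   comparable across implementations.
#' @name features_dwt
NULL

.db4 <- list(
  dec_lo = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
             -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
             0.7148465705529157, 0.2303778133088965),
  dec_hi = c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
             -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
             -0.0328830116668852, -0.010597401785069032),
  rec_lo = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
             -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
             0.0328830116668852, -0.010597401785069032),
  rec_hi = c(-0.010597401785069032, -0.0328830116668852, 0.030841381835560764,
             0.18703481171909309, -0.027983769416859854, -0.6308807679298589,
             0.7148465705529157, -0.2303778133088965))

# frequency bands (Hz) of D1..D4/A4 at 128 Hz sampling
DWT_BAND_MAP <- data.frame(
  component = c("D1", "D2", "D3", "D4", "A4"),
  band = c("gamma", "beta", "alpha", "theta", "delta"),
  low = c(32, 16, 8, 4, 0), high = c(64, 32, 16, 8, 4))

# symmetric (half-sample) extension by p samples each side
sym_extend <- function(x, p) {
  n <- length(x)
  c(rev(x[seq_len(min(p, n))]), x, rev(x[seq(n - min(p, n) + 1, n)]))
}

# standard full (linear) convolution
conv_full <- function(x, f) stats::convolve(x, rev(f), type = "open")

dwt_step <- function(x, mode = "symmetric",
                     lo = .db4$dec_lo, hi = .db4$dec_hi) {
  L <- length(lo)
  n <- length(x)
  if (mode == "symmetric") {
    ext <- sym_extend(x, L - 1L)
  } else {  # periodization: circular wrap, half-filter left phase
    if (n %% 2 != 0)
      stop("periodization mode needs an even signal length", call. = FALSE)
    ext <- c(x[(n - L / 2 + 1):n], x, x[seq_len(L / 2 - 1)])
  }
  a_valid <- conv_full(ext, lo)[L:length(ext)]
  d_valid <- conv_full(ext, hi)[L:length(ext)]
  idx <- seq(2, length(a_valid), by = 2)
  list(a = a_valid[idx], d = d_valid[idx])
}

circ_conv <- function(a, f) {
  n <- length(a)
  lin <- conv_full(a, f)
  res <- lin[seq_len(n)]
  wrap <- lin[(n + 1):length(lin)]
  res[seq_along(wrap)] <- res[seq_along(wrap)] + wrap
  res
}

idwt_step <- function(a, d, n_out, mode = "symmetric",
                      lo = .db4$rec_lo, hi = .db4$rec_hi) {
  up <- function(c) {
    u <- numeric(2 * length(c))
    u[seq(1, length(u), by = 2)] <- c
    u
  }
  if (mode == "symmetric") {
    y <- conv_full(up(a), lo) + conv_full(up(d), hi)
    trim <- length(lo) - 2L
    y[(trim + 1):(trim + n_out)]
  } else {
    y <- circ_conv(up(a), lo) + circ_conv(up(d), hi)
    rot <- length(lo) / 2 - 1L
    c(y[(rot + 1):length(y)], y[seq_len(rot)])
  }
}

#' Multi-level discrete wavelet decomposition of one channel
#'
#' @param x numeric vector (one epoch of one channel).
#' @param wavelet wavelet family; only `"db4"` is provided.
#' @param levels decomposition depth (default 4, mapping D1..D4/A4 onto the
#'   gamma/beta/alpha/theta/delta bands at 128 Hz).
#' @param sampling_rate sampling rate in Hz (metadata only).
#' @param mode boundary handling: `"symmetric"` extension (the default used
#'   for feature extraction) or `"periodization"` (circular wrap; the
#'   transform is then orthonormal, so coefficient energy equals signal
#'   energy exactly).
#' @return a `wavelet_decomposition`: list with coefficient arrays `D1`..`D<levels>`
#'   and `A<levels>`, plus `wavelet`, `levels`, `sampling_rate`, `input_length`.
#' @export
dwt_decompose <- function(x, wavelet = "db4", levels = 4, sampling_rate = 128,
                          mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  if (wavelet != "db4") stop("only the db4 wavelet is supported", call. = FALSE)
  min_len <- 2^levels
  if (length(x) < min_len)
    stop(sprintf("input too short for %d levels: need at least %d samples",
                 levels, min_len), call. = FALSE)
  details <- vector("list", levels)
  a <- x
  for (lvl in seq_len(levels)) {
    s <- dwt_step(a, mode)
    details[[lvl]] <- s$d
    a <- s$a
  }
  out <- c(stats::setNames(details, paste0("D", seq_len(levels))),
           stats::setNames(list(a), paste0("A", levels)))
  structure(list(coefficients = out, wavelet = wavelet, levels = levels,
                 sampling_rate = sampling_rate, input_length = length(x),
                 mode = mode),
            class = "wavelet_decomposition")
}

#' Inverse discrete wavelet transform
#'
#' @param decomposition a `wavelet_decomposition` from [dwt_decompose()].
#' @return the reconstructed signal (length `input_length`).
#' @export
dwt_reconstruct <- function(decomposition) {
  levels <- decomposition$levels
  mode <- if (is.null(decomposition$mode)) "symmetric" else decomposition$mode
  lens <- decomposition$input_length
  for (lvl in seq_len(levels))
    lens <- c(lens, if (mode == "symmetric")
      floor((lens[lvl] + length(.db4$dec_lo) - 1) / 2) else lens[lvl] / 2)
  a <- decomposition$coefficients[[paste0("A", levels)]]
  for (lvl in rev(seq_len(levels)))
    a <- idwt_step(a, decomposition$coefficients[[paste0("D", lvl)]],
                   n_out = lens[lvl], mode = mode)
  a
}

#' Shannon entropy of a signal's value distribution
#'
#' Values are binned into `n_bins` equal-width bins spanning the signal range;
#' the entropy is that of the bin-occupancy distribution, in bits. A constant
#' signal has zero entropy.
#'
#' @param x numeric vector.
#' @param n_bins number of histogram bins (default 16).
#' @return entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(x, n_bins = 16) {
  sum(entropy_profile(x, n_bins))
}

#' Per-bin information profile of a signal
#'
#' The sequence `-p_i * log2(p_i)` over the histogram bins (zeros for empty
#' bins); its sum is [shannon_entropy()]. This is the series summarized by the
#' statistical attributes in the wavelet feature block.
#'
#' @inheritParams shannon_entropy
#' @return numeric vector of length `n_bins`.
#' @export
entropy_profile <- function(x, n_bins = 16) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (n_bins < 2) stop("n_bins must be >= 2", call. = FALSE)
  rng <- range(x)
  prof <- numeric(n_bins)
  if (diff(rng) < .Machine$double.eps) {
    counts <- c(length(x), rep(0, n_bins - 1))
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    counts <- tabulate(pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                            n_bins), nbins = n_bins)
  }
  p <- counts / length(x)
  nz <- p > 0
  prof[nz] <- -p[nz] * log2(p[nz])
  prof
}

#' Ten statistical attributes of a series
#'
#' Mean, median, 25th/75th percentiles (linear interpolation), population
#' variance, standard deviation, root mean square, zero- and mean-crossing
#' rates (strict sign changes per consecutive pair; an exact hit on the
#' threshold breaks the crossing), and mean first difference.
#'
#' @param x numeric vector of length >= 2.
#' @return named numeric vector of the ten attributes.
#' @export
stat_attributes <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 samples (derivative undefined)", call. = FALSE)
  crossings <- function(v) {
    s <- sign(v)
    sum(s[-1] * s[-length(s)] < 0) / (n - 1)
  }
  v <- mean((x - mean(x))^2)
  c(mean = mean(x),
    median = stats::median(x),
    p25 = unname(stats::quantile(x, 0.25)),
    p75 = unname(stats::quantile(x, 0.75)),
    variance = v,
    std = sqrt(v),
    rms = sqrt(mean(x^2)),
    zero_crossing_rate = crossings(x),
    mean_crossing_rate = crossings(x - mean(x)),
    mean_derivative = mean(diff(x)))
}

STAT_NAMES <- c("mean", "median", "p25", "p75", "variance", "std", "rms",
                "zero_crossing_rate", "mean_crossing_rate", "mean_derivative")
DWT_COMPONENTS <- c("D1", "D2", "D3", "D4", "A4", "ENT")

#' Wavelet feature block for one epoch
#'
#' Per channel, six component series — the five coefficient arrays D1..D4, A4
#' and the entropy information profile — each summarized by the ten statistical
#' attributes: 10 channels x 6 components x 10 attributes = 600 named features
#' in deterministic order (channel-major, components D1,D2,D3,D4,A4,ENT).
#'
#' @param epoch an `eeg_epoch` with 10 channels.
#' @param n_bins histogram bins for the entropy profile.
#' @return named numeric vector of 600 features.
#' @export
extract_dwt_features <- function(epoch, n_bins = 16) {
  if (nrow(epoch$signal) != length(ANXIETY_CHANNELS))
    stop(sprintf("expected %d channels, got %d",
                 length(ANXIETY_CHANNELS), nrow(epoch$signal)), call. = FALSE)
  out <- lapply(epoch$channel_names, function(ch) {
    x <- epoch$signal[ch, ]
    dec <- dwt_decompose(x, sampling_rate = epoch$sampling_rate)
    series <- c(dec$coefficients[c("D1", "D2", "D3", "D4", "A4")],
                list(ENT = entropy_profile(x, n_bins)))
    vals <- unlist(lapply(series, stat_attributes), use.names = FALSE)
    names(vals) <- as.vector(outer(STAT_NAMES, DWT_COMPONENTS,
                                   function(a, comp) paste(ch, comp, a, sep = "_")))
    vals
  })
  unlist(out)
}

# per-channel band powers from the wavelet pyramid: mean square of the band's
# coefficient array (theta = D4, alpha = D3, beta = D2, gamma = D1)
dwt_band_powers <- function(epoch) {
  bands <- c(theta = "D4", alpha = "D3", beta = "D2", gamma = "D1")
  out <- t(vapply(epoch$channel_names, function(ch) {
    dec <- dwt_decompose(epoch$signal[ch, ], sampling_rate = epoch$sampling_rate)
    vapply(bands, function(comp) mean(dec$coefficients[[comp]]^2), 0)
  }, numeric(4)))
  colnames(out) <- names(bands)
  out
}
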