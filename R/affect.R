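#' @title Frontal valence/arousal asymmetry features
#' @description Eight affect features computed from frontal alpha and beta band
#'   powers, following the frontal-asymmetry tradition of EEG emotion research:
#'   four valence quantities (left/right beta-alpha ratio difference, log alpha
#'   asymmetry, alpha-beta difference, alpha/beta ratio difference) and four
#'   arousal quantities (alpha/beta ratio, its reciprocal, log2 beta/alpha
#'   ratio, negated summed log alpha). Several involve the midline electrode
#'   Fz, which the Emotiv EPOC montage does not carry; a configurable surrogate
#'   stands in for it.
#' @name affect
NULL

#' Sum of a band's power over a channel group
#'
#' @param bandpowers channels x bands numeric matrix (rownames = channels;
#'   columns include `alpha` and `beta`). The pseudo-channel `"Fz"` resolves
#'   through `fz_surrogate`.
#' @param channels channel names to sum over.
#' @param band `"alpha"` or `"beta"`.
#' @param fz_surrogate how to resolve Fz on an Fz-less montage:
#'   `"mean_f3_f4"` (midline interpolation from F3/F4), `"af3_af4"` (mean of
#'   AF3/AF4), or `"drop_term"` (omit Fz from the group).
#' @return summed band power.
#' @export
group_power <- function(bandpowers, channels, band = c("alpha", "beta"),
                        fz_surrogate = c("mean_f3_f4", "af3_af4", "drop_term")) {
  band <- match.arg(band)
  fz_surrogate <- match.arg(fz_surrogate)
  one <- function(ch) {
    if (ch == "Fz" && !"Fz" %in% rownames(bandpowers)) {
      switch(fz_surrogate,
             mean_f3_f4 = mean(bandpowers[c("F3", "F4"), band]),
             af3_af4 = mean(bandpowers[c("AF3", "AF4"), band]),
             drop_term = 0)
    } else {
      if (!ch %in% rownames(bandpowers))
        stop(sprintf("unknown channel '%s' in band-power set", ch), call. = FALSE)
      bandpowers[ch, band]
    }
  }
  sum(vapply(channels, one, 0))
}

#' Eight valence/arousal affect features from band powers
#'
#' With `a(...)`/`b(...)` the summed alpha/beta power over the named channels:
#' \itemize{
#' \item `valence1 = b(AF3,F3)/a(AF3,F3) - b(AF4,F4)/a(AF4,F4)`
#' \item `valence2 = ln a(Fz,AF3,F3) - ln a(Fz,AF4,F4)`
#' \item `valence3 = a(F4) - b(F3)`
#' \item `valence4 = a(F4)/b(F4) - a(F3)/b(F3)`
#' \item `arousal1 = a(AF3,AF4,F3,F4) / b(AF3,AF4,F3,F4)`
#' \item `arousal2 = 1 / arousal1`
#' \item `arousal3 = log2 [ b(Fz,AF4,F4,AF3,F3) / a(Fz,AF4,F4,AF3,F3) ]`
#' \item `arousal4 = -( ln a(Fz,AF4,F4) + ln a(Fz,AF3,F3) )`
#' }
#'
#' @param bandpowers channels x bands matrix with at least AF3, AF4, F3, F4
#'   rows and `alpha`, `beta` columns; powers must be strictly positive.
#' @param fz_surrogate see [group_power()].
#' @return named numeric vector `valence1..valence4, arousal1..arousal4`.
#' @export
affect_features <- function(bandpowers, fz_surrogate = "mean_f3_f4") {
  g <- function(channels, band)
    group_power(bandpowers, channels, band, fz_surrogate)
  need <- c("AF3", "AF4", "F3", "F4")
  pos <- vapply(need, function(ch)
    all(bandpowers[ch, c("alpha", "beta")] > 0), TRUE)
  if (!all(pos))
    stop("non-positive alpha/beta power on frontal channels; affect ratios/logs undefined",
         call. = FALSE)
  c(valence1 = g(c("AF3", "F3"), "beta") / g(c("AF3", "F3"), "alpha") -
      g(c("AF4", "F4"), "beta") / g(c("AF4", "F4"), "alpha"),
    valence2 = log(g(c("Fz", "AF3", "F3"), "alpha")) -
      log(g(c("Fz", "AF4", "F4"), "alpha")),
    valence3 = g("F4", "alpha") - g("F3", "beta"),
    valence4 = g("F4", "alpha") / g("F4", "beta") -
      g("F3", "alpha") / g("F3", "beta"),
    arousal1 = g(need, "alpha") / g(need, "beta"),
    arousal2 = g(need, "beta") / g(need, "alpha"),
    arousal3 = log2(g(c("Fz", "AF4", "F4", "AF3", "F3"), "beta") /
                      g(c("Fz", "AF4", "F4", "AF3", "F3"), "alpha")),
    arousal4 = -(log(g(c("Fz", "AF4", "F4"), "alpha")) +
                   log(g(c("Fz", "AF3", "F3"), "alpha"))))
}

#' Full feature vector for one epoch
#'
#' Extracts the method's feature block and appends the eight affect features,
#' computed from the same method's band powers (wavelet mode: mean square of
#' the band's coefficient array; spectral mode: integrated band power).
#'
#' @param epoch an `eeg_epoch` with 10 channels.
#' @param method `"dwt"` (600 + 8 = 608 features) or `"psd"` (60 + 8 = 68).
#' @param fz_surrogate see [group_power()].
#' @param ... passed to the block extractor.
#' @return named numeric feature vector.
#' @export
extract_features <- function(epoch, method = c("dwt", "psd"),
                             fz_surrogate = "mean_f3_f4", ...) {
  method <- match.arg(method)
  if (method == "dwt") {
    block <- extract_dwt_features(epoch, ...)
    bp <- dwt_band_powers(epoch)
  } else {
    block <- extract_psd_features(epoch, ...)
    bp <- psd_band_powers(epoch)
  }
  c(block, affect_features(bp, fz_surrogate))
}

#' Feature table for a list of epochs
#'
#' @param epochs list of `eeg_epoch`.
#' @param method `"dwt"` or `"psd"`.
#' @param ... passed to [extract_features()].
#' @return data frame with provenance columns (`subject_id`, `trial_id`,
#'   `epoch_index`) followed by the feature columns.
#' @export
feature_table <- function(epochs, method = c("dwt", "psd"), ...) {
  method <- match.arg(method)
  feats <- t(vapply(epochs, extract_features,
                    extract_features(epochs[[1]], method, ...), method, ...))
  prov <- data.frame(
    subject_id = vapply(epochs, function(e) as.integer(e$subject_id), 0L),
    trial_id = vapply(epochs, function(e) as.integer(e$trial_id), 0L),
    epoch_index = vapply(epochs, function(e) as.integer(e$epoch_index), 0L))
  cbind(prov, as.data.frame(feats))
}
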