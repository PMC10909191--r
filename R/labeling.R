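#' @title Binary anxiety labeling from SAM ratings and HAM-A scores
#' @name labeling
NULL

anxiety_label <- function(value, scheme) {
  structure(list(value = value, scheme = scheme), class = "anxiety_label")
}

#' Label a trial from SAM valence/arousal ratings
#'
#' A trial is anxious when valence <= 5 and arousal >= 5, except inside the
#' low-intensity carve-out (valence 4-5 with arousal 5-6), which is explicitly
#' non-anxious. With `carve_out_wins = FALSE` the carve-out is ignored and the
#' plain threshold rule applies.
#'
#' @param valence integer 1-9 (pleasantness).
#' @param arousal integer 1-9 (intensity).
#' @param carve_out_wins should the carve-out override the anxious rule?
#' @return an `anxiety_label` with `value` in `{"anxious", "non_anxious"}`.
#' @export
label_sam <- function(valence, arousal, carve_out_wins = TRUE) {
  if (!valence %in% 1:9 || !arousal %in% 1:9)
    stop("SAM ratings must be integers in 1..9", call. = FALSE)
  anxious <- valence <= 5 && arousal >= 5
  if (carve_out_wins && valence >= 4 && valence <= 5 && arousal >= 5 && arousal <= 6)
    anxious <- FALSE
  anxiety_label(if (anxious) "anxious" else "non_anxious", "SAM")
}

#' Label a subject from the HAM-A total score
#'
#' Scores 0-20 are non-anxious; scores above 20 are anxious. (The clinical
#' literature treats totals of 18+ as already severe; 20 is the detection
#' threshold used here.)
#'
#' @param score integer HAM-A total, 0-56.
#' @return an `anxiety_label`.
#' @export
label_hama <- function(score) {
  if (!score %in% 0:56)
    stop("HAM-A score must be an integer in 0..56", call. = FALSE)
  anxiety_label(if (score > 20) "anxious" else "non_anxious", "HAMA")
}

#' Broadcast trial/subject labels to epochs
#'
#' Every epoch of a trial carries the trial's SAM label; every epoch of a
#' subject carries the subject's HAM-A label.
#'
#' @param epochs list of `eeg_epoch`.
#' @param annotations data frame with `subject_id`, `trial_id`, `valence`,
#'   `arousal`, `hama_score` (one row per trial).
#' @param scheme `"sam"` or `"hama"`.
#' @return factor of labels (levels `non_anxious`, `anxious`), one per epoch.
#' @export
label_dataset <- function(epochs, annotations, scheme = c("sam", "hama")) {
  scheme <- match.arg(scheme)
  if (is.null(annotations) || nrow(annotations) == 0)
    stop("empty annotation table", call. = FALSE)
  key <- paste(annotations$subject_id, annotations$trial_id)
  labs <- vapply(epochs, function(ep) {
    i <- match(paste(ep$subject_id, ep$trial_id), key)
    if (is.na(i))
      stop(sprintf("no annotation for subject %s trial %s",
                   ep$subject_id, ep$trial_id), call. = FALSE)
    if (scheme == "sam")
      label_sam(annotations$valence[i], annotations$arousal[i])$value
    else
      label_hama(annotations$hama_score[i])$value
  }, "")
  factor(labs, levels = c("non_anxious", "anxious"))
}
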