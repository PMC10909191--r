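#' @title Synthetic EEG cohort generation
#' @description Generators producing Emotiv EPOC-style multi-channel EEG with a
#'   controllable anxious/non-anxious class structure, plus the matching SAM and
#'   HAM-A annotations, so the whole detection pipeline can be exercised without
#'   access to a real recording session.
#' @name synthetic_data
NULL

#' Emotiv EPOC montage (14 channels, headset order)
#' @export
EPOC_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                   "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

#' Frontal channels carrying the class-dependent band-power shift
#' @export
FRONTAL_CHANNELS <- c("AF3", "AF4", "F3", "F4", "F7", "F8", "FC5", "FC6")

# band-center oscillation frequencies (Hz) and baseline amplitudes (a.u.)
.sim_bands <- list(theta = c(freq = 6,  amp = 4),
                   alpha = c(freq = 10, amp = 8),
                   beta  = c(freq = 20, amp = 4),
                   gamma = c(freq = 35, amp = 2))

#' Simulation configuration
#'
#' Assembles and validates the parameters of the synthetic cohort. Defaults
#' mirror the structure of a DASPS-style acquisition: 6 one-minute trials per
#' subject, 14 EPOC channels sampled at 128 Hz.
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject trials recorded per subject (default 6).
#' @param trial_seconds trial duration in seconds (default 60).
#' @param sampling_rate sampling rate in Hz (default 128).
#' @param channel_names ordered electrode names (default the 14 EPOC channels).
#' @param effect_size dimensionless band-power shift between classes: anxious
#'   recordings have frontal beta amplitude scaled by `1 + effect_size` and
#'   frontal alpha scaled by `1 / (1 + effect_size)`.
#' @param noise_sd standard deviation of the additive Gaussian sensor noise.
#' @param anxious_fraction fraction of subjects in the anxious class.
#' @param seed master integer seed; each subject derives its own stream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 23, trials_per_subject = 6,
                       trial_seconds = 60, sampling_rate = 128,
                       channel_names = EPOC_CHANNELS,
                       effect_size = 1, noise_sd = 2,
                       anxious_fraction = 0.65, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              trials_per_subject = as.integer(trials_per_subject),
              trial_seconds = trial_seconds,
              sampling_rate = sampling_rate,
              channel_names = as.character(channel_names),
              effect_size = effect_size,
              noise_sd = noise_sd,
              anxious_fraction = anxious_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_subjects) || cfg$n_subjects < 1) bad("n_subjects", "must be >= 1")
  if (is.na(cfg$trials_per_subject) || cfg$trials_per_subject < 1)
    bad("trials_per_subject", "must be >= 1")
  if (cfg$trial_seconds <= 0) bad("trial_seconds", "must be > 0")
  if (cfg$sampling_rate <= 0) bad("sampling_rate", "must be > 0")
  max_freq <- max(vapply(.sim_bands, `[[`, numeric(1), "freq"))
  if (cfg$sampling_rate <= 2 * max_freq)
    bad("sampling_rate", sprintf("must exceed twice the highest synthesized frequency (%g Hz)",
                                 max_freq))
  if (anyDuplicated(cfg$channel_names)) bad("channel_names", "must be unique")
  if (cfg$effect_size < 0) bad("effect_size", "must be >= 0")
  if (cfg$noise_sd <= 0) bad("noise_sd", "must be > 0")
  if (cfg$anxious_fraction < 0 || cfg$anxious_fraction > 1)
    bad("anxious_fraction", "must lie in [0, 1]")
  invisible(cfg)
}

# Per-subject RNG stream derived from the master seed (stable under any
# ordering of subject simulation).
subject_seed <- function(cfg, subject_index) {
  as.integer((cfg$seed + 48271 * as.integer(subject_index)) %% .Machine$integer.max)
}

#' Generate one subject's synthetic EEG recordings
#'
#' Each trial is a sum of fixed-frequency band-center oscillations (theta 6 Hz,
#' alpha 10 Hz, beta 20 Hz, gamma 35 Hz) with uniform random phase per channel
#' and trial, plus white Gaussian noise. For an anxious subject the beta
#' amplitude is scaled up and the alpha amplitude down on the frontal channels
#' by the configured effect size; all random draws are identical for the two
#' class values of the same subject, so `effect_size = 0` makes the classes
#' bit-identical.
#'
#' @param config a [sim_config()].
#' @param subject_id subject index (1-based) used to derive the RNG stream.
#' @param anxious logical class flag.
#' @return list of `eeg_recording` objects, one per trial.
#' @export
generate_recording <- function(config, subject_id, anxious = FALSE) {
  validate_sim_config(config)
  n <- round(config$trial_seconds * config$sampling_rate)
  nch <- length(config$channel_names)
  frontal <- config$channel_names %in% FRONTAL_CHANNELS
  t <- (seq_len(n) - 1) / config$sampling_rate
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed(config, subject_id))
  lapply(seq_len(config$trials_per_subject), function(trial) {
    sig <- matrix(0, nrow = nch, ncol = n,
                  dimnames = list(config$channel_names, NULL))
    for (band in names(.sim_bands)) {
      f <- .sim_bands[[band]][["freq"]]
      amp <- rep(.sim_bands[[band]][["amp"]], nch)
      if (anxious) {
        if (band == "beta")  amp[frontal] <- amp[frontal] * (1 + config$effect_size)
        if (band == "alpha") amp[frontal] <- amp[frontal] / (1 + config$effect_size)
      }
      phase <- stats::runif(nch, 0, 2 * pi)
      sig <- sig + amp * sin(outer(phase, 2 * pi * f * t, `+`))
    }
    sig <- sig + matrix(stats::rnorm(nch * n, sd = config$noise_sd), nch, n)
    eeg_recording(sig, config$sampling_rate, config$channel_names,
                  subject_id = subject_id, trial_id = trial)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate SAM and HAM-A annotations consistent with class flags
#'
#' Anxious subjects receive a HAM-A total in 21..56 and per-trial SAM ratings
#' drawn from the anxious region of the valence/arousal grid (valence <= 5,
#' arousal >= 5, excluding the non-anxious carve-out); non-anxious subjects
#' receive HAM-A <= 20 and SAM ratings from the complement, so the labeling
#' module recovers the generating flags exactly.
#'
#' @param config a [sim_config()].
#' @param anxious_flags logical vector, one flag per subject.
#' @return data frame with one row per subject/trial: `subject_id`, `trial_id`,
#'   `valence`, `arousal`, `hama_score`, `anxious`.
#' @export
generate_annotations <- function(config, anxious_flags) {
  validate_sim_config(config)
  if (length(anxious_flags) != config$n_subjects)
    stop("need one anxious flag per subject", call. = FALSE)
  grid <- expand.grid(valence = 1:9, arousal = 1:9)
  lab <- mapply(function(v, a) label_sam(v, a)$value, grid$valence, grid$arousal)
  anx_cells <- grid[lab == "anxious", ]
  non_cells <- grid[lab == "non_anxious", ]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  out <- lapply(seq_len(config$n_subjects), function(s) {
    set.seed(subject_seed(config, s) %/% 2L + 1L)  # distinct from signal stream
    anx <- anxious_flags[s]
    cells <- if (anx) anx_cells else non_cells
    pick <- cells[sample.int(nrow(cells), config$trials_per_subject, replace = TRUE), ]
    data.frame(subject_id = s,
               trial_id = seq_len(config$trials_per_subject),
               valence = pick$valence, arousal = pick$arousal,
               hama_score = if (anx) sample(21:56, 1) else sample(0:20, 1),
               anxious = anx)
  })
  do.call(rbind, out)
}

#' Simulate a full cohort
#'
#' Draws subject class flags (first `round(anxious_fraction * n)` subjects
#' anxious, order fixed for reproducibility), then generates every recording
#' and the annotation table.
#'
#' @param config a [sim_config()].
#' @return list with `recordings` (flat list of `eeg_recording`, subjects x
#'   trials), `annotations` (data frame), and `anxious_flags`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  n_anx <- round(config$anxious_fraction * config$n_subjects)
  flags <- c(rep(TRUE, n_anx), rep(FALSE, config$n_subjects - n_anx))
  recs <- unlist(lapply(seq_len(config$n_subjects), function(s)
    generate_recording(config, s, flags[s])), recursive = FALSE)
  list(recordings = recs,
       annotations = generate_annotations(config, flags),
       anxious_flags = flags)
}
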