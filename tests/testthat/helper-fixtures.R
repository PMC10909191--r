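# in-code fixtures shared across test files

# a 10-channel, 1-s epoch of reproducible noise
make_epoch <- function(seed = 1, n = 128, channels = ANXIETY_CHANNELS) {
  set.seed(seed)
  sig <- matrix(rnorm(length(channels) * n), nrow = length(channels),
                dimnames = list(channels, NULL))
  structure(list(signal = sig, sampling_rate = 128, channel_names = channels,
                 subject_id = 1L, trial_id = 1L, epoch_index = 0L),
            class = "eeg_epoch")
}

# random strictly positive band-power set over the full montage
make_bandpowers <- function(seed = 1, channels = ANXIETY_CHANNELS) {
  set.seed(seed)
  bp <- matrix(runif(length(channels) * 4, 0.1, 10), nrow = length(channels),
               dimnames = list(channels, c("theta", "alpha", "beta", "gamma")))
  bp
}

# small simulated cohort, preprocessed to epochs, with labels
make_cohort_epochs <- function(seed = 1, n_subjects = 4, trials = 2,
                               trial_seconds = 5, effect_size = 2,
                               anxious_fraction = 0.5) {
  cfg <- sim_config(n_subjects = n_subjects, trials_per_subject = trials,
                    trial_seconds = trial_seconds, effect_size = effect_size,
                    anxious_fraction = anxious_fraction, seed = seed)
  cohort <- simulate_cohort(cfg)
  epochs <- preprocess(cohort$recordings)
  list(config = cfg, cohort = cohort, epochs = epochs)
}

# two well-separated Gaussian blobs for classifier sanity checks
make_blobs <- function(seed = 1, n_per_class = 60, p = 5, shift = 6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
             matrix(rnorm(n_per_class * p, mean = shift), ncol = p))
  colnames(x) <- paste0("f", seq_len(p))
  y <- factor(rep(c("non_anxious", "anxious"), each = n_per_class),
              levels = c("non_anxious", "anxious"))
  list(x = x, y = y)
}
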