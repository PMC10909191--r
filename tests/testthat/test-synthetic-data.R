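test_that("invalid simulation configs name the offending field", {
  expect_error(sim_config(n_subjects = 0), "n_subjects")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(anxious_fraction = 1.5), "anxious_fraction")
  expect_error(sim_config(channel_names = c("AF3", "AF3")), "channel_names")
  expect_error(sim_config(sampling_rate = 60), "sampling_rate")
})

test_that("recordings have the configured shape and are seed-deterministic", {
  cfg <- sim_config(n_subjects = 1, trial_seconds = 60, seed = 11)
  recs <- generate_recording(cfg, 1, anxious = TRUE)
  expect_length(recs, 6)
  expect_equal(dim(recs[[1]]$signal), c(14, 60 * 128))
  expect_identical(recs[[1]]$channel_names, EPOC_CHANNELS)
  recs2 <- generate_recording(cfg, 1, anxious = TRUE)
  expect_identical(recs, recs2)
})

test_that("zero effect size makes the classes bit-identical", {
  cfg <- sim_config(n_subjects = 1, trial_seconds = 2, effect_size = 0, seed = 5)
  a <- generate_recording(cfg, 1, anxious = TRUE)
  b <- generate_recording(cfg, 1, anxious = FALSE)
  expect_identical(a, b)
})

test_that("anxious recordings carry elevated frontal beta power (Monte Carlo)", {
  diffs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_subjects = 1, trials_per_subject = 1, trial_seconds = 2,
                      effect_size = 2, seed = s)
    beta_f34 <- function(rec) {
      mean(vapply(c("F3", "F4"), function(ch) {
        band_power(psd_estimate(rec$signal[ch, 1:256], 128), 13, 30)
      }, 0))
    }
    beta_f34(generate_recording(cfg, 1, TRUE)[[1]]) -
      beta_f34(generate_recording(cfg, 1, FALSE)[[1]])
  }, 0)
  expect_true(all(diffs > 0))
  expect_gt(mean(diffs), 0)
})

test_that("annotations respect the rating/score ranges by class", {
  cfg <- sim_config(n_subjects = 10, trials_per_subject = 6, trial_seconds = 1,
                    seed = 3)
  flags <- rep(c(TRUE, FALSE), 5)
  ann <- generate_annotations(cfg, flags)
  expect_equal(nrow(ann), 60)
  expect_true(all(ann$valence %in% 1:9 & ann$arousal %in% 1:9))
  expect_true(all(ann$hama_score[ann$anxious] > 20 & ann$hama_score[ann$anxious] <= 56))
  expect_true(all(ann$hama_score[!ann$anxious] <= 20 & ann$hama_score[!ann$anxious] >= 0))
})

test_that("labeling the generated annotations recovers the generating flags", {
  cfg <- sim_config(n_subjects = 8, trials_per_subject = 6, trial_seconds = 1,
                    seed = 9)
  flags <- c(rep(TRUE, 4), rep(FALSE, 4))
  ann <- generate_annotations(cfg, flags)
  sam <- mapply(function(v, a) label_sam(v, a)$value, ann$valence, ann$arousal)
  hama <- vapply(ann$hama_score, function(s) label_hama(s)$value, "")
  expect_identical(sam == "anxious", ann$anxious)
  expect_identical(hama == "anxious", ann$anxious)
})
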