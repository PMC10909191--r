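# single-level decomposition of the ramp 1..16, computed once with an
# independent wavelet toolbox (PyWavelets, symmetric mode) and frozen
RAMP16_A <- c(7.06453146258094, 4.2307361111496, 1.41360716607582,
              2.83605428034241, 5.6644814050886, 8.49290852983479,
              11.321335654581, 14.1497627793272, 16.9770990977617,
              19.810894449193, 22.6280233942668)
RAMP16_D <- c(0.0237131306262262, 0.0409620863958662, -0.0646752170220922,
              0, 0, 0, 0, 0,
              -0.0237131306262255, -0.0409620863958656, 0.0646752170220925)

test_that("db4 analysis matches the frozen independent oracle", {
  s <- anxeeg:::dwt_step(as.numeric(1:16))
  expect_lt(max(abs(s$a - RAMP16_A)), 1e-12)
  expect_lt(max(abs(s$d - RAMP16_D)), 1e-12)
})

test_that("four-level decomposition has the expected pyramid lengths", {
  dec <- dwt_decompose(rnorm(128))
  expect_named(dec$coefficients, c("D1", "D2", "D3", "D4", "A4"))
  expect_equal(vapply(dec$coefficients, length, 0L),
               c(D1 = 67L, D2 = 37L, D3 = 22L, D4 = 14L, A4 = 14L))
  decp <- dwt_decompose(rnorm(128), mode = "periodization")
  expect_equal(unname(vapply(decp$coefficients, length, 0L)),
               c(64L, 32L, 16L, 8L, 8L))
  expect_error(dwt_decompose(rnorm(8)), "at least 16")
})

test_that("decomposition is linear: zero in, zero out", {
  dec <- dwt_decompose(numeric(128))
  expect_true(all(abs(unlist(dec$coefficients)) == 0))
})

test_that("reconstruction is perfect for random inputs in both boundary modes", {
  for (seed in 1:25) {
    set.seed(seed)
    x <- rnorm(128)
    for (mode in c("symmetric", "periodization")) {
      xr <- dwt_reconstruct(dwt_decompose(x, mode = mode))
      expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
    }
  }
})

test_that("periodized db4 is orthonormal: coefficient energy equals signal energy", {
  for (seed in 1:10) {
    set.seed(seed)
    x <- rnorm(128)
    dec <- dwt_decompose(x, mode = "periodization")
    e <- sum(unlist(dec$coefficients)^2)
    expect_lt(abs(e - sum(x^2)) / sum(x^2), 1e-6)
  }
})

test_that("Shannon entropy matches hand-computed histogram cases", {
  expect_equal(shannon_entropy(rep(3.7, 50)), 0)
  expect_equal(shannon_entropy(c(0, 0, 1, 1), n_bins = 2), 1)
  expect_equal(shannon_entropy(c(0, 0, 0, 1), n_bins = 2),
               -(0.75 * log2(0.75) + 0.25 * log2(0.25)), tolerance = 1e-12)
  x <- rnorm(128)
  expect_lte(shannon_entropy(x, 16), log2(16))
  expect_gte(shannon_entropy(x, 16), 0)
  expect_error(shannon_entropy(numeric(0)), "empty")
  expect_error(shannon_entropy(1:5, n_bins = 1), "n_bins")
})

test_that("entropy is invariant under constant shifts (data-relative bins)", {
  set.seed(42)
  x <- rnorm(128)
  expect_equal(shannon_entropy(x), shannon_entropy(x + 100), tolerance = 1e-12)
  expect_equal(entropy_profile(x), entropy_profile(x - 55.5), tolerance = 1e-12)
  expect_equal(sum(entropy_profile(x)), shannon_entropy(x))
})

test_that("the ten statistical attributes match hand computations", {
  a <- stat_attributes(rep(2, 10))
  expect_equal(unname(a[c("mean", "median", "p25", "p75")]), rep(2, 4))
  expect_equal(unname(a[c("variance", "std")]), c(0, 0))
  expect_equal(unname(a["rms"]), 2)
  expect_equal(unname(a[c("zero_crossing_rate", "mean_crossing_rate",
                          "mean_derivative")]), c(0, 0, 0))
  b <- stat_attributes(c(1, -1, 1, -1))
  expect_equal(unname(b["mean"]), 0)
  expect_equal(unname(b["rms"]), 1)
  expect_equal(unname(b["zero_crossing_rate"]), 1)
  expect_equal(unname(b["mean_derivative"]), -2 / 3)
  c3 <- stat_attributes(c(1, 2, 3, 4))
  expect_equal(unname(c3["mean"]), 2.5)
  expect_equal(unname(c3["variance"]), 1.25)  # population variance
  expect_equal(unname(c3["std"]), sqrt(1.25))
  expect_equal(unname(c3["mean_derivative"]), 1)
  expect_error(stat_attributes(1), "2 samples")
})

test_that("attribute invariants hold for random series", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- stat_attributes(rnorm(64))
    expect_equal(unname(a["std"]), sqrt(unname(a["variance"])))
    expect_lte(unname(a["p25"]), unname(a["median"]))
    expect_lte(unname(a["median"]), unname(a["p75"]))
    expect_gte(unname(a["rms"]), 0)
    expect_true(all(a[c("zero_crossing_rate", "mean_crossing_rate")] >= 0 &
                      a[c("zero_crossing_rate", "mean_crossing_rate")] <= 1))
  }
})

test_that("the wavelet feature block has 600 uniquely named features, 608 with affect", {
  ep <- make_epoch(1)
  feats <- extract_dwt_features(ep)
  expect_length(feats, 600)
  expect_false(anyDuplicated(names(feats)) > 0)
  full <- extract_features(ep, "dwt")
  expect_length(full, 608)
  expect_identical(names(full)[601:608],
                   c(paste0("valence", 1:4), paste0("arousal", 1:4)))
  # determinism and name stability across epochs
  expect_identical(extract_features(ep, "dwt"), full)
  expect_identical(names(extract_features(make_epoch(2), "dwt")), names(full))
  # wrong channel count rejected
  bad <- make_epoch(1, channels = ANXIETY_CHANNELS[1:9])
  expect_error(extract_dwt_features(bad), "channels")
})
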