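test_that("group power sums the named channels and resolves Fz surrogates", {
  bp <- make_bandpowers(1)
  expect_equal(group_power(bp, "F3", "alpha"), bp["F3", "alpha"])
  expect_equal(group_power(bp, c("AF3", "F3"), "beta"),
               bp["AF3", "beta"] + bp["F3", "beta"])
  expect_equal(group_power(bp, c("F3", "AF3"), "beta"),
               group_power(bp, c("AF3", "F3"), "beta"))
  expect_equal(group_power(bp, "Fz", "alpha"),
               mean(bp[c("F3", "F4"), "alpha"]))
  expect_equal(group_power(bp, "Fz", "alpha", fz_surrogate = "af3_af4"),
               mean(bp[c("AF3", "AF4"), "alpha"]))
  expect_equal(group_power(bp, c("Fz", "F3"), "alpha", fz_surrogate = "drop_term"),
               bp["F3", "alpha"])
  expect_error(group_power(bp, "Cz", "alpha"), "Cz")
})

test_that("equal band powers give the symmetry zeros and units", {
  bp <- matrix(1, nrow = 10, ncol = 4,
               dimnames = list(ANXIETY_CHANNELS,
                               c("theta", "alpha", "beta", "gamma")))
  af <- affect_features(bp)
  expect_equal(unname(af[c("valence1", "valence2", "valence4")]), rep(0, 3))
  expect_equal(unname(af["valence3"]), 0)
  expect_equal(unname(af[c("arousal1", "arousal2")]), c(1, 1))
  expect_equal(unname(af["arousal3"]), 0)
  expect_equal(unname(af["arousal4"]), -2 * log(3), tolerance = 1e-12)
})

test_that("hemisphere swap flips valence asymmetries and fixes arousal", {
  for (seed in 1:20) {
    bp <- make_bandpowers(seed)
    sw <- bp
    sw[c("AF3", "AF4", "F3", "F4"), ] <- bp[c("AF4", "AF3", "F4", "F3"), ]
    a <- affect_features(bp)
    b <- affect_features(sw)
    expect_equal(unname(b["valence1"]), -unname(a["valence1"]), tolerance = 1e-12)
    expect_equal(unname(b["valence2"]), -unname(a["valence2"]), tolerance = 1e-12)
    for (nm in c("arousal1", "arousal2", "arousal3"))
      expect_equal(unname(b[nm]), unname(a[nm]), tolerance = 1e-12)
  }
})

test_that("the two arousal ratios are exact reciprocals (property over 1000 draws)", {
  for (seed in 1:1000) {
    bp <- make_bandpowers(seed)
    af <- affect_features(bp)
    expect_lt(abs(af[["arousal1"]] * af[["arousal2"]] - 1), 1e-12)
  }
})

test_that("ratio features are scale invariant; log features shift as predicted", {
  bp <- make_bandpowers(7)
  a <- affect_features(bp)
  b <- affect_features(bp * 10)
  for (nm in c("valence1", "valence4", "arousal1", "arousal2", "arousal3"))
    expect_equal(b[[nm]], a[[nm]], tolerance = 1e-12)
  expect_equal(b[["valence2"]], a[["valence2"]], tolerance = 1e-12)
  expect_equal(b[["arousal4"]], a[["arousal4"]] - 2 * log(10), tolerance = 1e-12)
  expect_equal(b[["valence3"]], 10 * a[["valence3"]], tolerance = 1e-12)
})

test_that("non-positive frontal powers are rejected", {
  bp <- make_bandpowers(2)
  bp["F3", "alpha"] <- 0
  expect_error(affect_features(bp), "non-positive")
})
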