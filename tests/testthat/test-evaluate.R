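test_that("waveform metrics reproduce their closed forms", {
  ref <- c(80, 90, 120, 100, 85)
  m <- waveformMetrics(ref, ref)
  expect_equal(m$mse, 0)
  expect_equal(m$mae, 0)
  expect_equal(m$r2, 1)

  m1 <- waveformMetrics(ref, ref + 1)
  expect_equal(m1$mse, 1)
  expect_equal(m1$mae, 1)

  m0 <- waveformMetrics(ref, rep(mean(ref), 5))
  expect_equal(m0$r2, 0)

  expect_error(waveformMetrics(ref, ref[-1]), "lengths differ")
  expect_error(waveformMetrics(rep(1, 5), rep(1, 5)), "constant reference")
})

test_that("Bland-Altman reproduces closed forms and the brute-force recomputation", {
  ref <- c(100, 110, 120)
  ba0 <- blandAltman(ref, ref)
  expect_equal(agreementBias(ba0), 0)
  expect_equal(unname(loaLimits(ba0)), c(0, 0))

  ba2 <- blandAltman(ref + 2, ref)
  expect_equal(agreementBias(ba2), 2)
  expect_equal(ba2@sdDiff, 0)
  expect_equal(unname(loaLimits(ba2)), c(2, 2))

  # d = {-1, 0, 1}: sample SD 1, LoA +/- 1.96
  ba <- blandAltman(c(99, 110, 121), c(100, 110, 120))
  expect_equal(agreementBias(ba), 0)
  expect_equal(ba@sdDiff, 1)
  expect_equal(unname(loaLimits(ba)), c(-1.96, 1.96))

  # oracle: brute-force recomputation on random pairs
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(2:40, 1)
    est <- rnorm(n, 120, 10)
    refv <- rnorm(n, 118, 9)
    b <- blandAltman(est, refv)
    d <- est - refv
    s <- sqrt(sum((d - mean(d))^2) / (n - 1))
    expect_equal(agreementBias(b), mean(d))
    expect_equal(b@sdDiff, s)
    expect_equal(unname(loaLimits(b)),
      c(mean(d) - 1.96 * s, mean(d) + 1.96 * s))
    expect_equal(loaWidth(b), 2 * 1.96 * s)
  }

  expect_error(blandAltman(1, 1), "2 complete pairs")
  expect_error(blandAltman(c(NA, 1, 2), c(1, NA, 2)), "2 complete pairs")
})

test_that("limits-of-agreement widths match the published window-level values", {
  expect_equal(loaWidth(c(-13.09, 17.39)), 30.48)
  expect_equal(loaWidth(c(-21.96, 17.34)), 39.30)
  expect_equal(loaWidth(c(5, 5)), 0)
})

test_that("evaluating the reference waveform against itself gives perfect agreement", {
  cohort <- tinyCohort()[1:2]
  # identity 'model': compare the reference-derived estimates to themselves
  for (rec in cohort) {
    ref <- bpWaveform(rec)[51:nSamples(rec)]
    out <- extractBP(ref)
    w <- out$windows
    ok <- !is.na(w$sbp)
    ba <- blandAltman(w$sbp[ok], w$sbp[ok])
    expect_equal(agreementBias(ba), 0)
    expect_equal(loaWidth(ba), 0)
    m <- waveformMetrics(ref, ref)
    expect_equal(m$r2, 1)
  }
})

test_that("cohort evaluation pools windows and pairs one estimate per recording", {
  cohort <- tinyCohort()
  m <- buildModel(modelConfig(), seed = 4)
  # untrained model with an identity scaler: structure, not quality
  ev <- evaluateCohort(m, cohort[1:3])
  expect_equal(nrow(ev$waveform), 3L)
  expect_equal(nrow(ev$recording_table), 3L)
  expect_true(all(c("sbp_est", "sbp_ref", "dbp_est", "dbp_ref") %in%
    names(ev$window_table)))
  # 30 s recordings, 50 samples trimmed -> 6 windows each
  expect_equal(nrow(ev$window_table), 18L)
  expect_true(all(table(ev$window_table$participant_id) == 6L))
  # reference windows carry values (the reference waveform is in-gate)
  expect_true(all(!is.na(ev$window_table$sbp_ref)))
})
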