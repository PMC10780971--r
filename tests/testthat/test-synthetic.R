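test_that("simulated recordings have the contracted geometry", {
  p <- participantParams(seed = 4)
  rec <- simulateParticipant(p, duration = 480, fs = 100)
  expect_equal(nSamples(rec), 48000)
  expect_equal(dim(loadCells(rec)), c(4L, 48000L))
  expect_equal(samplingRate(rec), 100)
  expect_equal(recordingDuration(rec), 480)

  rec2 <- simulateParticipant(p, duration = 2.5, fs = 1000)
  expect_equal(nSamples(rec2), 2500)
})

test_that("simulation rejects invalid inputs", {
  p <- participantParams()
  expect_error(simulateParticipant(p, duration = -1), "positive")
  expect_error(simulateParticipant(p, duration = 10, fs = 250), "100 or 1000")
  expect_error(participantParams(sbp_level = 90, dbp_level = 95), "exceed")
  expect_error(participantParams(sbp_level = 155), "100, 150")
  expect_error(participantParams(dbp_level = 55), "60, 100")
  expect_error(participantParams(noise_sd = -1), "non-negative")
})

test_that("noiseless 60 bpm waveform is exactly periodic with BP extrema at the levels", {
  p <- participantParams(
    sbp_level = 125, dbp_level = 75, heart_rate = 60, hr_jitter_sd = 0,
    resp_amplitude = 0, noise_sd = 0, drift_amplitude = 0, seed = 1
  )
  rec <- simulateParticipant(p, duration = 10, fs = 100)
  bp <- bpWaveform(rec)
  expect_equal(max(bp), 125, tolerance = 1e-6)
  expect_equal(min(bp), 75, tolerance = 1e-6)
  # period exactly 1.0 s = 100 samples
  expect_equal(bp[1:800], bp[101:900], tolerance = 1e-9)
})

test_that("simulation is a pure function of its parameters", {
  p <- participantParams(seed = 77)
  r1 <- simulateParticipant(p, duration = 5)
  r2 <- simulateParticipant(p, duration = 5)
  expect_identical(loadCells(r1), loadCells(r2))
  expect_identical(bpWaveform(r1), bpWaveform(r2))

  c1 <- simulateCohort(3, duration = 5, masterSeed = 9)
  c2 <- simulateCohort(3, duration = 5, masterSeed = 9)
  expect_identical(lapply(c1, bpWaveform), lapply(c2, bpWaveform))
  # and RNG state outside is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulateCohort(2, duration = 2, masterSeed = 1))
  expect_identical(before, .Random.seed)
})

test_that("cohort generation yields distinct participants inside the amplitude gates", {
  cohort <- simulateCohort(38, duration = 20, masterSeed = 7)
  expect_length(cohort, 38)
  expect_length(unique(vapply(cohort, participantId, "")), 38L)
  for (rec in cohort) {
    bp <- bpWaveform(rec)
    expect_gt(min(bp), 60)
    expect_lt(max(bp), 150)
    expect_gt(max(bp), 100)   # systolic peaks inside the systolic gate
    expect_lt(min(bp), 100)   # diastolic troughs inside the diastolic gate
  }
})

test_that("a linear probe can regress BP from flattened windows across participants", {
  # learnability floor: a ridge regressor on flattened noiseless windows,
  # evaluated pooled over held-out participants (far below the LSTM)
  cohort <- simulateCohort(14, duration = 30, masterSeed = 31,
    noise_sd = 0, drift_amplitude = 0)
  flat <- function(rec, take = 400) {
    ds <- buildWindows(rec)
    idx <- round(seq(1, nWindows(ds), length.out = take))
    X <- t(vapply(idx, function(i) as.numeric(windowInput(ds, i)),
      numeric(4 * 50)))
    list(X = X, y = windowTargets(ds)[idx])
  }
  trn <- lapply(cohort[1:12], flat)
  X <- cbind(1, do.call(rbind, lapply(trn, `[[`, "X")))
  y <- unlist(lapply(trn, `[[`, "y"))
  beta <- solve(crossprod(X) + 1e-3 * nrow(X) * diag(ncol(X)),
    crossprod(X, y))
  tst <- lapply(cohort[13:14], flat)
  yTe <- unlist(lapply(tst, `[[`, "y"))
  pred <- cbind(1, do.call(rbind, lapply(tst, `[[`, "X"))) %*% beta
  r2 <- 1 - sum((yTe - pred)^2) / sum((yTe - mean(yTe))^2)
  expect_gt(r2, 0.5)
})

test_that("per-participant seeds derive deterministically and within integer range", {
  s1 <- deriveSeed(7, 1:38)
  s2 <- deriveSeed(7, 1:38)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 < 2^31))
  expect_gt(length(unique(s1)), 37L)
  expect_false(identical(deriveSeed(7, 1), deriveSeed(8, 1)))
})

test_that("recordings round-trip through the CSV format", {
  rec <- simulateParticipant(participantParams(seed = 12), duration = 2)
  f <- tempfile(fileext = ".csv")
  writeRecordingCSV(rec, f)
  back <- readRecordingCSV(f, participantId = participantId(rec))
  expect_equal(samplingRate(back), 100)
  expect_equal(bpWaveform(back), bpWaveform(rec), tolerance = 1e-5)
  expect_equal(loadCells(back), loadCells(rec), tolerance = 1e-5,
    ignore_attr = TRUE)
  unlink(f)
})
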