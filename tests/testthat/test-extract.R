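test_that("sine-wave extrema are detected at the gated amplitudes", {
  t <- seq(0, 5 - 1e-9, by = 1 / 100)
  x <- 100 + 20 * sin(2 * pi * 1.2 * t)
  ev <- detectEvents(x)
  sys <- ev[ev$kind == "systolic", ]
  dia <- ev[ev$kind == "diastolic", ]
  expect_equal(nrow(sys), 6L)
  expect_equal(nrow(dia), 6L)
  expect_true(all(abs(sys$amplitude - 120) < 0.1))
  expect_true(all(abs(dia$amplitude - 80) < 0.1))
  expect_equal(ev$time, (ev$index - 1) / 100)
})

test_that("degenerate and gated waveforms behave as specified", {
  expect_equal(nrow(detectEvents(rep(110, 100))), 0L)
  expect_error(detectEvents(c(1, 2)), "too short")

  # peaks at 165 exceed the systolic gate; troughs at 75 are kept
  t <- seq(0, 5 - 1e-9, by = 1 / 100)
  x <- 120 + 45 * sin(2 * pi * 1 * t)
  ev <- detectEvents(x)
  expect_equal(sum(ev$kind == "systolic"), 0L)
  dia <- ev[ev$kind == "diastolic", ]
  expect_gt(nrow(dia), 0L)
  expect_true(all(abs(dia$amplitude - 75) < 0.1))
})

test_that("pre-refractory detection equals the brute-force extrema scan", {
  set.seed(99)
  for (rep in 1:25) {
    L <- sample(100:1500, 1)
    # smooth random waveform wandering through both gates
    x <- 105 + 25 * sin(2 * pi * 1.1 * (1:L) / 100 + runif(1, 0, 6)) +
      cumsum(rnorm(L, 0, 0.3))
    ev <- detectEvents(x, applyRefractory = FALSE)
    or <- bruteExtrema(x)
    expect_equal(ev$index[ev$kind == "systolic"], or$sys)
    expect_equal(ev$index[ev$kind == "diastolic"], or$dia)
  }
})

test_that("refractory thinning keeps the more extreme event and enforces separation", {
  # two close peaks: 120 at sample 30 and 123 at sample 60 -> keep 123
  x <- rep(110, 200)
  x[29:31] <- c(119, 120, 119)
  x[59:61] <- c(122, 123, 122)
  x[150:152] <- c(124, 125, 124)
  ev <- detectEvents(x)
  sys <- ev[ev$kind == "systolic", ]
  expect_equal(sys$index, c(60L, 151L))
  expect_equal(sys$amplitude, c(123, 125))

  # equal amplitudes closer than 50 samples: earlier one wins
  x2 <- rep(110, 200)
  x2[39:41] <- c(119, 120, 119)
  x2[69:71] <- c(119, 120, 119)
  ev2 <- detectEvents(x2)
  expect_equal(ev2$index[ev2$kind == "systolic"], 40L)

  # refractory invariant on random smooth signals
  set.seed(7)
  for (rep in 1:20) {
    L <- sample(500:2000, 1)
    x <- 110 + 30 * sin(2 * pi * 2 * (1:L) / 100) + cumsum(rnorm(L, 0, 0.5))
    ev <- detectEvents(x)
    for (kind in c("systolic", "diastolic")) {
      idx <- ev$index[ev$kind == kind]
      if (length(idx) > 1) expect_true(all(diff(idx) >= 50))
    }
  }
})

test_that("window aggregation assigns events to half-open five-second tiles", {
  ev <- data.frame(
    index = c(101, 601), time = c(1, 6), amplitude = c(118, 122),
    kind = "systolic"
  )
  w <- windowEstimates(ev, duration = 10)
  expect_equal(nrow(w), 2L)
  expect_equal(w$sbp, c(118, 122))
  expect_equal(w$n_sys_events, c(1L, 1L))
  expect_true(all(is.na(w$dbp)))

  # six events uniformly over one window average to their common amplitude
  ev2 <- data.frame(
    index = seq(50, 450, by = 80), time = seq(0.49, 4.49, by = 0.8),
    amplitude = 120, kind = "systolic"
  )
  w2 <- windowEstimates(ev2, duration = 5)
  expect_equal(nrow(w2), 1L)
  expect_equal(w2$sbp, 120)

  # a 12 s recording yields 2 full windows plus an included partial one
  w3 <- windowEstimates(ev[0, ], duration = 12)
  expect_equal(nrow(w3), 3L)
  expect_equal(w3$window_start, c(0, 5, 10))

  # an event exactly on a boundary belongs to the later window
  evb <- data.frame(index = 501, time = 5, amplitude = 110, kind = "systolic")
  wb <- windowEstimates(evb, duration = 10)
  expect_true(is.na(wb$sbp[1]))
  expect_equal(wb$sbp[2], 110)
})

test_that("recording estimates skip absent windows and fail on empty input", {
  wins <- data.frame(
    window_start = c(0, 5, 10), sbp = c(120, NA, 126), dbp = c(80, 82, NA),
    n_sys_events = c(2L, 0L, 1L), n_dia_events = c(2L, 1L, 0L)
  )
  est <- recordingEstimate(wins)
  expect_equal(est$sbp_mean, 123)
  expect_equal(est$dbp_mean, 81)
  expect_equal(est$n_windows_sbp, 2L)
  expect_equal(est$n_windows_dbp, 2L)

  wins$sbp <- NA_real_
  wins$dbp <- NA_real_
  expect_error(recordingEstimate(wins), "no usable windows")

  expect_equal(recordingEstimate(data.frame(sbp = c(118, 122), dbp = NA))$sbp_mean,
    120)
})

test_that("adding an event moves the window estimate toward its amplitude", {
  base <- data.frame(index = c(101, 201), time = c(1, 2),
    amplitude = c(120, 122), kind = "systolic")
  w0 <- windowEstimates(base, duration = 5)$sbp
  extra <- rbind(base, data.frame(index = 301, time = 3, amplitude = 140,
    kind = "systolic"))
  w1 <- windowEstimates(extra, duration = 5)$sbp
  expect_gt(w1, w0)
  expect_lt(w1, 140)
})

test_that("end-to-end extraction on a noiseless participant recovers its levels", {
  p <- participantParams(
    sbp_level = 125, dbp_level = 75, noise_sd = 0, drift_amplitude = 0,
    hr_jitter_sd = 0, seed = 6
  )
  rec <- simulateParticipant(p, duration = 30)
  out <- extractBP(bpWaveform(rec))
  expect_lt(abs(out$recording$sbp_mean - 125), 1)
  expect_lt(abs(out$recording$dbp_mean - 75), 1)
})
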