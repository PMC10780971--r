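test_that("window counts, targets and indices follow the sliding-matrix contract", {
  rec <- loadCellRecording("A", 100, matrix(rnorm(4 * 60), 4, 60), rnorm(60))
  ds <- buildWindows(rec, N = 50)
  expect_equal(nWindows(ds), 10L)
  expect_equal(targetIndices(ds)[[1]], 51:60)
  expect_equal(windowTargets(ds), bpWaveform(rec)[51:60])

  rec2 <- simulateParticipant(participantParams(seed = 2), duration = 480)
  expect_equal(nWindows(buildWindows(rec2)), 48000L - 50L)

  expect_error(buildWindows(
    loadCellRecording("B", 100, matrix(0, 4, 50), rep(0, 50))), "shorter")
  expect_error(buildWindows(
    loadCellRecording("C", 1000, matrix(0, 4, 500), rep(0, 500))), "100 Hz")
})

test_that("window content matches direct slicing, including ramp channels", {
  # channel j holds the ramp j + i (i = 0-based sample index)
  L <- 70
  lc <- t(sapply(1:4, function(j) j + 0:(L - 1)))
  rec <- loadCellRecording("R", 100, lc, rnorm(L))
  ds <- buildWindows(rec, N = 50)
  w1 <- windowInput(ds, 1)  # predicts sample 51: samples 1..50 (i = 0..49)
  expect_equal(dim(w1), c(4L, 50L))
  for (j in 1:4) expect_equal(w1[j, ], j + 0:49)

  # brute-force equivalence over every window of a random recording
  rec2 <- loadCellRecording("S", 100, matrix(rnorm(4 * 65), 4, 65), rnorm(65))
  ds2 <- buildWindows(rec2, N = 50)
  for (k in seq_len(nWindows(ds2))) {
    expect_identical(windowInput(ds2, k),
      loadCells(rec2)[, k:(k + 49), drop = FALSE])
  }
})

test_that("datasets concatenate across recordings without spanning boundaries", {
  recs <- lapply(1:3, function(i)
    loadCellRecording(paste0("P", i), 100,
      matrix(rnorm(4 * 60), 4, 60), rnorm(60)))
  ds <- buildWindowsCohort(recs)
  expect_equal(nWindows(ds), 30L)
  expect_equal(participantId(ds), c("P1", "P2", "P3"))
  # window 11 is the first window of the second recording
  expect_identical(windowInput(ds, 11), loadCells(recs[[2]])[, 1:50])
  expect_equal(windowTargets(ds)[11], bpWaveform(recs[[2]])[51])
})

test_that("participant partition respects sizes, disjointness and the seed", {
  ids <- sprintf("P%02d", 1:38)
  sp <- partitionParticipants(ids, seed = 7)
  expect_length(sp$train, 22L)
  expect_length(sp$val, 6L)
  expect_length(sp$test, 10L)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_length(intersect(sp$val, sp$test), 0L)

  sp2 <- partitionParticipants(sprintf("x%d", 1:10), c(0.6, 0.2, 0.2), seed = 3)
  expect_equal(lengths(sp2), c(train = 6L, val = 2L, test = 2L))

  expect_identical(partitionParticipants(ids, seed = 11),
    partitionParticipants(ids, seed = 11))
  expect_false(identical(partitionParticipants(ids, seed = 11),
    partitionParticipants(ids, seed = 12)))

  expect_error(partitionParticipants(c("a", "b"), seed = 1), "at least 3")
  expect_error(partitionParticipants(ids, c(0.5, 0.2, 0.2), seed = 1),
    "summing to 1")
  expect_error(partitionParticipants(c("a", "b", "c", "d"),
    c(0.95, 0.04, 0.01), seed = 1), "empty")
})
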