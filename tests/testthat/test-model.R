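test_that("the default architecture has exactly 18,871 trainable parameters", {
  m <- buildModel(modelConfig(), seed = 1)
  expect_identical(nTrainableParams(m), 18871L)
  # closed form: three LSTM layers + single-output dense
  expect_identical(
    lstmParamCount(30, 4) + 2L * lstmParamCount(30, 30) + (30L + 1L),
    18871L
  )
})

test_that("parameter counts follow the closed form for arbitrary configurations", {
  cfg <- modelConfig(lstm_units = 1, n_lstm_layers = 1, input_steps = 5,
    input_features = 1)
  m <- buildModel(cfg, seed = 1)
  expect_identical(nTrainableParams(m), 12L + 2L)  # 4*(1*(1+1)+1) + dense

  cfg2 <- modelConfig(lstm_units = 7, n_lstm_layers = 2, input_steps = 10,
    input_features = 3)
  expect_identical(
    nTrainableParams(buildModel(cfg2, seed = 1)),
    lstmParamCount(7, 3) + lstmParamCount(7, 7) + 8L
  )
  expect_error(modelConfig(lstm_units = 0), "positive")
  expect_error(modelConfig(output_dim = 2), "single-output")
})

test_that("prediction emits one scalar per window and matches a pure-R forward pass", {
  cfg <- modelConfig(lstm_units = 3, n_lstm_layers = 2, input_steps = 5,
    input_features = 4)
  m <- buildModel(cfg, seed = 9)
  set.seed(11)
  L <- 12
  rec <- loadCellRecording("X", 100, matrix(rnorm(4 * L), 4, L), rnorm(L))
  ds <- buildWindows(rec, N = 5)
  p <- predictWindows(m, ds)
  expect_length(p, 7L)
  pr <- vapply(seq_len(7), function(k)
    lstmForwardR(m@weights, t(loadCells(rec)[, k:(k + 4)])), 0)
  expect_equal(p, pr, tolerance = 1e-5)
})

test_that("backpropagation matches finite differences of the loss", {
  cfg <- modelConfig(lstm_units = 3, n_lstm_layers = 2, input_steps = 5,
    input_features = 2)
  m <- buildModel(cfg, seed = 9)
  set.seed(42)
  L <- 13
  sig <- list(matrix(rnorm(2 * L), 2, L))
  tgt <- list(rnorm(L - 5))
  g <- bedpress:::lstm_grad_cpp(m@weights, sig, tgt, 5L)
  eps <- 1e-2
  an <- unlist(g$grads)
  fd <- numeric(length(an))
  pos <- 0
  for (wi in seq_along(m@weights)) {
    for (k in seq_along(m@weights[[wi]])) {
      pos <- pos + 1
      wp <- m@weights; wp[[wi]][k] <- wp[[wi]][k] + eps
      wm <- m@weights; wm[[wi]][k] <- wm[[wi]][k] - eps
      fd[pos] <- (bedpress:::lstm_grad_cpp(wp, sig, tgt, 5L)$loss -
        bedpress:::lstm_grad_cpp(wm, sig, tgt, 5L)$loss) / (2 * eps)
    }
  }
  expect_gt(sum(an * fd) / sqrt(sum(an^2) * sum(fd^2)), 0.999)
  big <- abs(fd) + abs(an) > 1e-3  # above single-precision FD noise
  expect_gt(sum(big), 20)
  expect_lt(max(abs(fd - an)[big] / (abs(fd) + abs(an))[big]), 0.02)
})

test_that("the target scaler is a train-only affine map with exact inverse", {
  sc <- fitTargetScaler(c(60, 100, 160))
  expect_equal(scaleTargets(sc, c(60, 160)), c(0, 1))
  x <- runif(50, 40, 200)
  expect_equal(unscaleTargets(sc, scaleTargets(sc, x)), x, tolerance = 1e-12)
  # values outside the training range extrapolate without clipping
  expect_gt(scaleTargets(sc, 170), 1)
  expect_error(fitTargetScaler(rep(5, 4)), "constant")
})

test_that("a zero-weight model predicts the dense bias everywhere", {
  m <- buildModel(modelConfig(), seed = 1)
  m@weights <- lapply(m@weights, function(w) w * 0)
  m@weights[[11]] <- 3.25  # dense bias
  rec <- simulateParticipant(participantParams(seed = 8), duration = 2)
  out <- reconstructBP(m, rec)
  expect_equal(length(bpWaveform(out)), 150L)
  expect_true(all(abs(bpWaveform(out) - 3.25) < 1e-5))
  expect_equal(out@startIndex, 50L)
})

test_that("reconstruction is shift-equivariant", {
  m <- buildModel(modelConfig(), seed = 3)
  rec <- simulateParticipant(participantParams(seed = 8), duration = 4)
  s <- 25
  L <- nSamples(rec)
  shifted <- loadCellRecording("S", 100,
    loadCells(rec)[, (s + 1):L], bpWaveform(rec)[(s + 1):L])
  full <- bpWaveform(reconstructBP(m, rec))
  part <- bpWaveform(reconstructBP(m, shifted))
  expect_equal(full[(s + 1):length(full)], part, tolerance = 1e-5)
})

test_that("training records losses, checkpoints the best epoch and learns", {
  cohort <- tinyCohort()
  tr <- buildWindowsCohort(cohort[1:2])
  va <- buildWindowsCohort(cohort[3])
  tcfg <- trainConfig(epochs = 5, seed = 1)
  fit <- trainModel(buildModel(seed = 1), tr, va, tcfg)
  h <- fit$history
  expect_length(trainLoss(h), 5L)
  expect_length(valLoss(h), 5L)
  expect_identical(bestEpoch(h), which.min(valLoss(h)))
  # checkpointed weights dominate the last epoch on validation data
  expect_lte(datasetMSE(fit$model, va),
    datasetMSE(fit$model, va, weights = h@lastWeights) + 1e-9)
  # learning: validation error improves on the initialization
  expect_lt(min(valLoss(h)), valLoss(h)[1])
  # and the model carries the train-fitted scaler
  expect_equal(fit$model@scaler$min, min(windowTargets(tr)))
})

test_that("training enforces participant disjointness and dataset validity", {
  cohort <- tinyCohort()
  tr <- buildWindowsCohort(cohort[1:2])
  expect_error(
    trainModel(buildModel(seed = 1), tr, buildWindowsCohort(cohort[2]),
      trainConfig(epochs = 1)),
    "both train and validation"
  )
  mismatched <- buildWindowsCohort(cohort[3], N = 40L)
  expect_error(
    trainModel(buildModel(seed = 1), tr, mismatched, trainConfig(epochs = 1)),
    "window length"
  )
})

test_that("training is reproducible under a fixed seed", {
  cohort <- tinyCohort()
  tr <- buildWindowsCohort(cohort[1])
  va <- buildWindowsCohort(cohort[3])
  f1 <- trainModel(buildModel(seed = 2), tr, va, trainConfig(epochs = 2, seed = 5))
  f2 <- trainModel(buildModel(seed = 2), tr, va, trainConfig(epochs = 2, seed = 5))
  expect_identical(valLoss(f1$history), valLoss(f2$history))
  expect_identical(f1$model@weights, f2$model@weights)
})

test_that("models round-trip through save/load with sidecar metadata", {
  m <- buildModel(modelConfig(lstm_units = 4, n_lstm_layers = 2,
    input_steps = 6, input_features = 4), seed = 3)
  m@scaler <- list(min = 62.5, range = 80)
  d <- tempfile()
  saveModel(m, d, split = list(train = c("P01", "P02"), val = "P03",
    test = "P04"))
  expect_true(file.exists(file.path(d, "weights.rds")))
  expect_true(file.exists(file.path(d, "model.json")))
  back <- loadModel(d)
  expect_equal(back@weights, m@weights)
  expect_equal(back@scaler, m@scaler)
  expect_equal(back@config, m@config)
  # loaded model predicts identically
  rec <- loadCellRecording("X", 100, matrix(rnorm(4 * 20), 4, 20),
    rnorm(20))
  ds <- buildWindows(rec, N = 6)
  expect_equal(predictWindows(back, ds), predictWindows(m, ds))
  unlink(d, recursive = TRUE)
})
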