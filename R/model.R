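## The stacked-LSTM regressor: construction, target normalization,
## training with best-validation checkpointing, and waveform
## reconstruction.

#' Model architecture configuration
#'
#' Defaults give the reference architecture: three stacked 30-unit LSTM
#' layers (the first two returning full sequences, the last returning its
#' final step) over 50-step, 4-feature input windows, followed by a
#' single-unit linear dense layer — 18,871 trainable parameters in total.
#'
#' @param lstm_units hidden units per LSTM layer.
#' @param n_lstm_layers number of stacked LSTM layers.
#' @param input_steps window length N (time steps).
#' @param input_features channels per time step.
#' @param output_dim output dimension (must be 1).
#' @return A validated list of class `ModelConfig`.
#' @examples
#' nTrainableParams(buildModel(modelConfig(), seed = 1))
#' @export
modelConfig <- function(lstm_units = 30L, n_lstm_layers = 3L,
                        input_steps = 50L, input_features = 4L,
                        output_dim = 1L) {
  cfg <- list(
    lstm_units = as.integer(lstm_units),
    n_lstm_layers = as.integer(n_lstm_layers),
    input_steps = as.integer(input_steps),
    input_features = as.integer(input_features),
    output_dim = as.integer(output_dim)
  )
  if (any(unlist(cfg) < 1L)) stop("all configuration fields must be positive")
  if (cfg$output_dim != 1L) stop("only a single-output dense layer is supported")
  class(cfg) <- "ModelConfig"
  cfg
}

#' Training configuration
#'
#' @param epochs number of training epochs (default 300).
#' @param batch_size minibatch size (default 256).
#' @param lr,beta1,beta2,eps Adam hyperparameters (framework-conventional
#'   defaults).
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param normalize_targets min-max normalize targets to \[0, 1\] using the
#'   training set only (default `TRUE`); predictions are always returned
#'   in mmHg via the inverse map.
#' @param zscore_inputs per-recording z-scoring of the load-cell channels
#'   (default `FALSE`: inputs are used in raw filtered units).
#' @param verbose print per-epoch losses.
#' @return A validated list of class `TrainConfig`.
#' @export
trainConfig <- function(epochs = 300L, batch_size = 256L, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7,
                        seed = 1L, normalize_targets = TRUE,
                        zscore_inputs = FALSE, verbose = FALSE) {
  cfg <- list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
    seed = as.integer(seed), normalize_targets = isTRUE(normalize_targets),
    zscore_inputs = isTRUE(zscore_inputs), verbose = isTRUE(verbose),
    loss = "mean_squared_error", optimizer = "adam", init = "glorot_normal"
  )
  if (cfg$epochs < 1L || cfg$batch_size < 1L)
    stop("epochs and batch_size must be >= 1")
  class(cfg) <- "TrainConfig"
  cfg
}

glorotNormal <- function(fanIn, fanOut, nr, nc) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / (fanIn + fanOut))), nr, nc)
}

#' Build the LSTM regressor with Glorot-normal initialization
#'
#' Kernels are drawn from N(0, 2 / (fan_in + fan_out)); biases start at
#' zero except the forget-gate block, which starts at one (the usual
#' stabilizing convention for LSTM training).
#'
#' @param cfg a [modelConfig()].
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A [BPRegressor-class] with freshly initialized weights.
#' @export
buildModel <- function(cfg = modelConfig(), seed = NULL) {
  stopifnot(inherits(cfg, "ModelConfig"))
  init <- function() {
    u <- cfg$lstm_units
    w <- list()
    inDim <- cfg$input_features
    for (l in seq_len(cfg$n_lstm_layers)) {
      b <- numeric(4 * u)
      b[(u + 1):(2 * u)] <- 1  # forget-gate bias
      w[[length(w) + 1]] <- glorotNormal(inDim, 4 * u, inDim, 4 * u)
      w[[length(w) + 1]] <- glorotNormal(u, 4 * u, u, 4 * u)
      w[[length(w) + 1]] <- b
      inDim <- u
    }
    w[[length(w) + 1]] <- glorotNormal(u, cfg$output_dim, u, cfg$output_dim)
    w[[length(w) + 1]] <- 0
    w
  }
  weights <- if (is.null(seed)) init() else withSeed(seed, init())
  new("BPRegressor", config = unclass(cfg), weights = weights,
    scaler = list(), inputScaling = "none")
}

#' Count trainable parameters
#'
#' @param model a [BPRegressor-class].
#' @return Integer: the total number of weight entries. Per LSTM layer the
#'   closed form is `4 * (units * (features + units) + units)`; the dense
#'   layer adds `units + 1`.
#' @export
nTrainableParams <- function(model) {
  stopifnot(is(model, "BPRegressor"))
  sum(vapply(model@weights, length, 0L))
}

#' Fit a min-max target scaler on training targets
#'
#' The affine map `(y - min) / (max - min)` is fit on the training set
#' only and reused unchanged for validation and test data (values outside
#' the training range map outside \[0, 1\]; there is no clipping).
#'
#' @param targets numeric training targets, mmHg.
#' @return `list(min =, range =)`.
#' @export
fitTargetScaler <- function(targets) {
  rng <- range(targets)
  if (diff(rng) == 0) stop("targets are constant; scaler undefined")
  list(min = rng[1], range = diff(rng))
}

#' @rdname fitTargetScaler
#' @param scaler a fitted scaler (empty list = identity).
#' @param y values to transform / back-transform.
#' @export
scaleTargets <- function(scaler, y) {
  if (!length(scaler)) return(y)
  (y - scaler$min) / scaler$range
}

#' @rdname fitTargetScaler
#' @export
unscaleTargets <- function(scaler, y) {
  if (!length(scaler)) return(y)
  y * scaler$range + scaler$min
}

zscoreRows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, sd)
  sdv[sdv == 0] <- 1
  (m - mu) / sdv
}

prepSignals <- function(ds, inputScaling) {
  if (identical(inputScaling, "zscore")) lapply(ds@signals, zscoreRows)
  else ds@signals
}

#' Train the regressor with best-validation checkpointing
#'
#' Minimizes the mean squared error over minibatches with Adam; after each
#' epoch the validation MSE is computed and the weights of the epoch with
#' the lowest validation error are kept (ties keep the earliest epoch).
#' The returned model carries those checkpointed weights, never the final
#' ones. Training and validation participants must be disjoint.
#'
#' @param model a [BPRegressor-class] (freshly built or pre-trained).
#' @param trainDs,valDs [WindowDataset-class] objects.
#' @param tcfg a [trainConfig()].
#' @return `list(model =, history =)`: the checkpointed
#'   [BPRegressor-class] (with the target scaler fitted on the training
#'   set) and a [TrainHistory-class].
#' @examples
#' \donttest{
#' cohort <- simulateCohort(3, duration = 30, masterSeed = 1)
#' tr <- buildWindowsCohort(cohort[1:2])
#' va <- buildWindowsCohort(cohort[3])
#' fit <- trainModel(buildModel(seed = 1), tr, va,
#'   trainConfig(epochs = 2, seed = 1))
#' bestEpoch(fit$history)
#' }
#' @export
trainModel <- function(model, trainDs, valDs, tcfg = trainConfig()) {
  stopifnot(is(model, "BPRegressor"), is(trainDs, "WindowDataset"),
    is(valDs, "WindowDataset"), inherits(tcfg, "TrainConfig"))
  if (nWindows(trainDs) < 1 || nWindows(valDs) < 1)
    stop("empty dataset")
  shared <- intersect(trainDs@participantIds, valDs@participantIds)
  if (length(shared))
    stop("participants in both train and validation sets: ",
      paste(shared, collapse = ", "))
  if (trainDs@N != model@config$input_steps ||
    valDs@N != model@config$input_steps)
    stop("dataset window length does not match the model configuration")

  inputScaling <- if (tcfg$zscore_inputs) "zscore" else "none"
  scaler <- if (tcfg$normalize_targets)
    fitTargetScaler(windowTargets(trainDs)) else list()

  res <- lstm_train_cpp(
    model@weights,
    prepSignals(trainDs, inputScaling),
    lapply(trainDs@targets, scaleTargets, scaler = scaler),
    prepSignals(valDs, inputScaling),
    lapply(valDs@targets, scaleTargets, scaler = scaler),
    trainDs@N, tcfg$epochs, tcfg$batch_size,
    tcfg$lr, tcfg$beta1, tcfg$beta2, tcfg$eps, tcfg$seed, tcfg$verbose
  )

  history <- new("TrainHistory",
    trainLoss = res$train_loss, valLoss = res$val_loss,
    bestEpoch = as.integer(res$best_epoch),
    bestWeights = res$best_weights, lastWeights = res$last_weights
  )
  trained <- new("BPRegressor",
    config = model@config, weights = res$best_weights,
    scaler = scaler, inputScaling = inputScaling
  )
  list(model = trained, history = history)
}

#' Validation MSE of a weight set
#'
#' Evaluates the mean squared error of a model (or an explicit weight
#' list, e.g. `lastWeights` of a [TrainHistory-class]) on a dataset, on
#' the same (normalized) scale used during training.
#'
#' @param model a [BPRegressor-class] supplying config, scaler and input
#'   scaling.
#' @param ds a [WindowDataset-class].
#' @param weights optional weight list overriding `model`'s weights.
#' @return Mean squared error (normalized scale if the model has a
#'   scaler).
#' @export
datasetMSE <- function(model, ds, weights = NULL) {
  stopifnot(is(model, "BPRegressor"), is(ds, "WindowDataset"))
  if (is.null(weights)) weights <- model@weights
  lstm_eval_cpp(
    weights, prepSignals(ds, model@inputScaling),
    lapply(ds@targets, scaleTargets, scaler = model@scaler), ds@N
  )
}

#' Predict one scalar per window
#'
#' @param model a trained [BPRegressor-class].
#' @param ds a [WindowDataset-class].
#' @return Numeric vector of predictions in mmHg, one per window in
#'   dataset order.
#' @export
predictWindows <- function(model, ds) {
  stopifnot(is(model, "BPRegressor"), is(ds, "WindowDataset"))
  sig <- prepSignals(ds, model@inputScaling)
  yhat <- unlist(lapply(sig, function(s)
    lstm_predict_cpp(model@weights, s, ds@N)), use.names = FALSE)
  unscaleTargets(model@scaler, yhat)
}

#' Reconstruct the full BP waveform of a recording
#'
#' Applies the model to every 1-sample-shifted window of the recording:
#' output sample k estimates the BP at source sample `N + k` (1-based), so
#' the whole waveform is reconstructed except for the initial N samples.
#'
#' @param model a trained [BPRegressor-class].
#' @param rec a [LoadCellRecording-class] at 100 Hz.
#' @return A [ReconstructedBP-class].
#' @export
reconstructBP <- function(model, rec) {
  stopifnot(is(model, "BPRegressor"), is(rec, "LoadCellRecording"))
  if (rec@fs != 100) stop("reconstruction expects a 100 Hz recording")
  N <- model@config$input_steps
  if (nSamples(rec) <= N) stop("recording shorter than N + 1 samples")
  lc <- if (model@inputScaling == "zscore") zscoreRows(rec@loadCells)
    else rec@loadCells
  yhat <- lstm_predict_cpp(model@weights, lc, N)
  new("ReconstructedBP",
    values = unscaleTargets(model@scaler, yhat),
    startIndex = as.integer(N), fs = rec@fs,
    participantId = rec@participantId
  )
}

#' Save / load a trained regressor
#'
#' `saveModel` writes the weights in R's native serialized format
#' (`weights.rds`) together with a human-readable JSON sidecar
#' (`model.json`) holding the architecture configuration, the target
#' scaler, the input-scaling mode and, optionally, the training history
#' summary and split membership. `loadModel` restores the model.
#'
#' @param model a [BPRegressor-class].
#' @param dir directory to create/use.
#' @param history optional [TrainHistory-class] to summarize in the
#'   sidecar.
#' @param split optional list of participant-id vectors to record.
#' @return `saveModel`: `dir`, invisibly; `loadModel`: a
#'   [BPRegressor-class].
#' @export
saveModel <- function(model, dir, history = NULL, split = NULL) {
  stopifnot(is(model, "BPRegressor"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model@weights, file.path(dir, "weights.rds"))
  sidecar <- list(
    config = model@config,
    scaler = model@scaler,
    input_scaling = model@inputScaling
  )
  if (!is.null(history)) {
    sidecar$training <- list(
      epochs_run = length(trainLoss(history)),
      best_epoch = bestEpoch(history),
      best_val_mse = valLoss(history)[bestEpoch(history)]
    )
  }
  if (!is.null(split)) sidecar$split <- split
  jsonlite::write_json(sidecar, file.path(dir, "model.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "model.json"),
    simplifyVector = TRUE)
  weights <- readRDS(file.path(dir, "weights.rds"))
  scaler <- sidecar$scaler
  if (length(scaler)) scaler <- list(min = scaler$min, range = scaler$range)
  else scaler <- list()
  new("BPRegressor",
    config = as.list(sidecar$config),
    weights = weights,
    scaler = scaler,
    inputScaling = sidecar$input_scaling
  )
}
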