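## End-to-end experiment: simulate (or load) -> preprocess -> split ->
## window -> train -> reconstruct -> extract -> evaluate.

#' Experiment configuration
#'
#' One nested list holding every tunable of the pipeline, with the
#' reference defaults: 0.05-35 Hz band, analysis rate 100 Hz, window
#' N = 50 samples, three 30-unit LSTM layers, 300 epochs, batch 256,
#' amplitude gates \[100, 150\] / \[60, 100\] mmHg, 50-sample refractory,
#' 5-s aggregation windows, and 22/38-6/38-10/38 split fractions.
#' Serializes losslessly to YAML via [writeExperimentConfig()].
#'
#' @param n_participants cohort size for simulation.
#' @param duration recording duration, seconds.
#' @param fs simulation sampling rate, 100 or 1000 Hz.
#' @param noise_sd,drift_amplitude simulator noise settings.
#' @param master_seed seed for cohort generation.
#' @param low_cut,high_cut,filter_order band-pass settings.
#' @param N window length, samples.
#' @param lstm_units,n_lstm_layers architecture settings.
#' @param epochs,batch_size,lr training settings.
#' @param train_seed seed for initialization and shuffling.
#' @param split_fractions train/val/test fractions (sum to 1).
#' @param split_seed seed for the participant permutation.
#' @param sys_gate,dia_gate,refractory,agg_window extraction settings.
#' @return A nested list of class `ExperimentConfig`.
#' @export
experimentConfig <- function(n_participants = 38L, duration = 480,
                             fs = 100, noise_sd = 0.05,
                             drift_amplitude = 0.2, master_seed = 7L,
                             low_cut = 0.05, high_cut = 35,
                             filter_order = 4L, N = 50L,
                             lstm_units = 30L, n_lstm_layers = 3L,
                             epochs = 300L, batch_size = 256L, lr = 1e-3,
                             train_seed = 1L,
                             split_fractions = c(22, 6, 10) / 38,
                             split_seed = 7L,
                             sys_gate = c(100, 150), dia_gate = c(60, 100),
                             refractory = 50L, agg_window = 5) {
  cfg <- list(
    simulate = list(
      n_participants = as.integer(n_participants), duration = duration,
      fs = fs, noise_sd = noise_sd, drift_amplitude = drift_amplitude,
      master_seed = as.integer(master_seed)
    ),
    filter = list(low_cut = low_cut, high_cut = high_cut,
      order = as.integer(filter_order)),
    windowing = list(N = as.integer(N),
      split_fractions = split_fractions,
      split_seed = as.integer(split_seed)),
    model = list(lstm_units = as.integer(lstm_units),
      n_lstm_layers = as.integer(n_lstm_layers)),
    train = list(epochs = as.integer(epochs),
      batch_size = as.integer(batch_size), lr = lr,
      seed = as.integer(train_seed)),
    extract = list(sys_gate = sys_gate, dia_gate = dia_gate,
      refractory = as.integer(refractory), agg_window = agg_window)
  )
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' Read / write an experiment configuration as YAML
#'
#' @param cfg an [experimentConfig()].
#' @param path YAML file path.
#' @return `readExperimentConfig` returns the `ExperimentConfig`;
#'   `writeExperimentConfig` returns `path` invisibly. The round trip is
#'   the identity.
#' @export
writeExperimentConfig <- function(cfg, path) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(experimentConfig, list(
    n_participants = cfg$simulate$n_participants,
    duration = cfg$simulate$duration, fs = cfg$simulate$fs,
    noise_sd = cfg$simulate$noise_sd,
    drift_amplitude = cfg$simulate$drift_amplitude,
    master_seed = cfg$simulate$master_seed,
    low_cut = cfg$filter$low_cut, high_cut = cfg$filter$high_cut,
    filter_order = cfg$filter$order, N = cfg$windowing$N,
    lstm_units = cfg$model$lstm_units,
    n_lstm_layers = cfg$model$n_lstm_layers,
    epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
    lr = cfg$train$lr, train_seed = cfg$train$seed,
    split_fractions = cfg$windowing$split_fractions,
    split_seed = cfg$windowing$split_seed,
    sys_gate = cfg$extract$sys_gate, dia_gate = cfg$extract$dia_gate,
    refractory = cfg$extract$refractory,
    agg_window = cfg$extract$agg_window
  ))
}

#' Run the full experiment
#'
#' Simulates (or accepts) a cohort, conditions every recording, splits
#' participants disjointly, builds sliding-window datasets, trains the
#' regressor with best-validation checkpointing, and evaluates waveform
#' reconstruction and SBP/DBP agreement on the held-out test
#' participants.
#'
#' @param cfg an [experimentConfig()].
#' @param cohort optional pre-made list of [LoadCellRecording-class]
#'   objects; if `NULL`, a cohort is simulated from `cfg$simulate`.
#' @param outDir optional directory; when given, the report (JSON), the
#'   paired estimate tables (CSV) and the config echo (YAML) are written
#'   there.
#' @param verbose print stage progress.
#' @return A report list: `config`, `split`, `history`
#'   ([TrainHistory-class]), `model` ([BPRegressor-class]), and the
#'   [evaluateCohort()] results under `evaluation`.
#' @export
runExperiment <- function(cfg = experimentConfig(), cohort = NULL,
                          outDir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  stage <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "),
    ...)

  if (is.null(cohort)) {
    stage("simulating cohort of ", cfg$simulate$n_participants)
    cohort <- simulateCohort(
      cfg$simulate$n_participants, cfg$simulate$duration, cfg$simulate$fs,
      cfg$simulate$master_seed, cfg$simulate$noise_sd,
      cfg$simulate$drift_amplitude
    )
  }

  stage("preprocessing")
  spec <- filterSpec(cfg$filter$low_cut, cfg$filter$high_cut,
    cfg$filter$order)
  cohort <- lapply(cohort, preprocessRecording, spec = spec)

  stage("splitting participants")
  split <- partitionParticipants(
    vapply(cohort, participantId, ""),
    cfg$windowing$split_fractions, cfg$windowing$split_seed
  )

  stage("windowing")
  N <- cfg$windowing$N
  trainDs <- buildWindowsCohort(cohort[split$train], N)
  valDs <- buildWindowsCohort(cohort[split$val], N)

  stage("training for ", cfg$train$epochs, " epochs")
  mcfg <- modelConfig(
    lstm_units = cfg$model$lstm_units,
    n_lstm_layers = cfg$model$n_lstm_layers,
    input_steps = N
  )
  model <- buildModel(mcfg, seed = cfg$train$seed)
  tcfg <- trainConfig(
    epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
    lr = cfg$train$lr, seed = cfg$train$seed
  )
  fit <- trainModel(model, trainDs, valDs, tcfg)

  stage("evaluating on ", length(split$test), " test recordings")
  evalRes <- evaluateCohort(
    fit$model, cohort[split$test], cfg$extract$agg_window,
    cfg$extract$sys_gate, cfg$extract$dia_gate, cfg$extract$refractory
  )

  report <- list(
    config = cfg, split = split, history = fit$history,
    model = fit$model, evaluation = evalRes
  )
  if (!is.null(outDir)) writeReport(report, outDir)
  report
}

baAsList <- function(ba) {
  if (is.null(ba)) return(NULL)
  list(
    bias = ba@bias, sd_diff = ba@sdDiff, loa_lower = ba@loaLower,
    loa_upper = ba@loaUpper, width = loaWidth(ba), n = ba@n,
    level = ba@level, kind = ba@kind
  )
}

#' Write an experiment report to disk
#'
#' Emits `report.json` (metrics, agreement, split, training summary,
#' config echo), `window_estimates.csv` and `recording_estimates.csv`, and
#' `config.yaml`.
#'
#' @param report the list returned by [runExperiment()].
#' @param outDir output directory (created if missing).
#' @return `outDir`, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ev <- report$evaluation
  json <- list(
    config = unclass(report$config),
    split = report$split,
    training = list(
      epochs_run = length(trainLoss(report$history)),
      best_epoch = bestEpoch(report$history),
      best_val_mse = valLoss(report$history)[bestEpoch(report$history)],
      final_val_mse = tail(valLoss(report$history), 1)
    ),
    waveform_metrics = ev$waveform,
    agreement = list(
      window_sbp = baAsList(ev$window_sbp),
      window_dbp = baAsList(ev$window_dbp),
      recording_sbp = baAsList(ev$recording_sbp),
      recording_dbp = baAsList(ev$recording_dbp)
    )
  )
  jsonlite::write_json(json, file.path(outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(ev$window_table,
    file.path(outDir, "window_estimates.csv"), row.names = FALSE)
  utils::write.csv(ev$recording_table,
    file.path(outDir, "recording_estimates.csv"), row.names = FALSE)
  writeExperimentConfig(report$config, file.path(outDir, "config.yaml"))
  invisible(outDir)
}
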