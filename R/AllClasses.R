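#' Synchronized load-cell + blood-pressure recording
#'
#' Container for one participant's time-synchronized recording: four
#' load-cell (BCG) channels and a continuous arterial blood-pressure
#' waveform sharing a single sampling rate.
#'
#' @slot participantId single character identifier.
#' @slot fs sampling frequency in Hz.
#' @slot loadCells numeric matrix with 4 rows (channels LC0..LC3) and one
#'   column per sample.
#' @slot bp numeric vector of blood-pressure samples in mmHg, same length
#'   as the load-cell channels.
#'
#' @seealso [loadCellRecording()] for the user-facing constructor.
#' @exportClass LoadCellRecording
setClass("LoadCellRecording",
  representation(
    participantId = "character",
    fs = "numeric",
    loadCells = "matrix",
    bp = "numeric"
  )
)

setValidity("LoadCellRecording", function(object) {
  msg <- character()
  if (length(object@participantId) != 1L || is.na(object@participantId))
    msg <- c(msg, "participantId must be a single non-missing string")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (nrow(object@loadCells) != 4L)
    msg <- c(msg, "loadCells must have exactly 4 rows (channels LC0..LC3)")
  if (ncol(object@loadCells) != length(object@bp))
    msg <- c(msg, "load-cell channels and bp must share one length")
  if (anyNA(object@loadCells) || anyNA(object@bp))
    msg <- c(msg, "signals must not contain missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a LoadCellRecording
#'
#' @param participantId participant identifier.
#' @param fs sampling frequency, Hz.
#' @param loadCells 4 x L numeric matrix (rows = channels LC0..LC3).
#' @param bp numeric vector of length L, mmHg.
#' @return A [LoadCellRecording-class] object.
#' @examples
#' rec <- loadCellRecording("P01", 100, matrix(0, 4, 200), rep(80, 200))
#' nSamples(rec)
#' @export
loadCellRecording <- function(participantId, fs, loadCells, bp) {
  new("LoadCellRecording",
    participantId = as.character(participantId), fs = as.numeric(fs),
    loadCells = loadCells, bp = as.numeric(bp)
  )
}

#' Sliding-window regression dataset
#'
#' Pairs each strictly causal window of N load-cell samples (4 channels)
#' with the blood-pressure sample immediately following it. Windows are
#' represented implicitly: the object stores the source channel matrices and
#' materializes an individual window on demand via [windowInput()], so the
#' (heavily overlapping) window tensor never exists in memory. Windows never
#' span recording boundaries; datasets from several recordings are
#' concatenated with [concatWindows()].
#'
#' For a source recording of length L there are L - N windows; window k
#' (1-based) covers samples `[k, k+N-1]` and predicts the BP sample at
#' index `k + N`.
#'
#' @slot signals list of 4 x L numeric matrices, one per source recording.
#' @slot targets list of numeric vectors (mmHg), element r of length
#'   `ncol(signals[[r]]) - N`.
#' @slot participantIds character vector, one id per source recording.
#' @slot N window length in samples.
#'
#' @exportClass WindowDataset
setClass("WindowDataset",
  representation(
    signals = "list",
    targets = "list",
    participantIds = "character",
    N = "integer"
  )
)

setValidity("WindowDataset", function(object) {
  msg <- character()
  if (length(object@N) != 1L || object@N < 1L)
    msg <- c(msg, "N must be a single positive integer")
  if (length(object@signals) != length(object@targets) ||
    length(object@signals) != length(object@participantIds))
    msg <- c(msg, "signals, targets and participantIds must align")
  for (r in seq_along(object@signals)) {
    L <- ncol(object@signals[[r]])
    if (nrow(object@signals[[r]]) != 4L)
      msg <- c(msg, "each signal matrix must have 4 rows")
    if (L <= object@N)
      msg <- c(msg, "each recording must be longer than N samples")
    else if (length(object@targets[[r]]) != L - object@N)
      msg <- c(msg, "each target vector must have length L - N")
  }
  if (length(msg)) msg else TRUE
})

#' Stacked-LSTM blood-pressure regressor
#'
#' Holds the architecture configuration, the flat list of weight arrays
#' (per LSTM layer: input kernel, recurrent kernel, bias; then the dense
#' kernel and bias), and the fitted target scaler used to map normalized
#' network outputs back to mmHg.
#'
#' @slot config list as returned by [modelConfig()].
#' @slot weights list of numeric arrays.
#' @slot scaler empty list (identity) or `list(min=, range=)` fitted on
#'   training targets.
#' @slot inputScaling character, `"none"` or `"zscore"` (per-recording
#'   z-scoring of load-cell channels before prediction).
#'
#' @exportClass BPRegressor
setClass("BPRegressor",
  representation(
    config = "list",
    weights = "list",
    scaler = "list",
    inputScaling = "character"
  ),
  prototype(scaler = list(), inputScaling = "none")
)

#' Training history with best-epoch checkpoint
#'
#' Per-epoch training and validation mean-squared errors (on the normalized
#' target scale when target normalization is enabled), the index of the
#' epoch with the lowest validation error, and the weight checkpoints from
#' that epoch and from the final epoch.
#'
#' @slot trainLoss numeric, one value per epoch.
#' @slot valLoss numeric, one value per epoch.
#' @slot bestEpoch integer, argmin of `valLoss` (ties resolved to the
#'   earliest epoch).
#' @slot bestWeights,lastWeights weight lists as in [BPRegressor-class].
#'
#' @exportClass TrainHistory
setClass("TrainHistory",
  representation(
    trainLoss = "numeric",
    valLoss = "numeric",
    bestEpoch = "integer",
    bestWeights = "list",
    lastWeights = "list"
  )
)

setValidity("TrainHistory", function(object) {
  msg <- character()
  if (length(object@trainLoss) != length(object@valLoss))
    msg <- c(msg, "trainLoss and valLoss must have one value per epoch")
  if (length(object@trainLoss) > 0 &&
    (object@bestEpoch < 1L || object@bestEpoch > length(object@valLoss)))
    msg <- c(msg, "bestEpoch out of range")
  if (length(msg)) msg else TRUE
})

#' Reconstructed blood-pressure waveform
#'
#' The model's estimate of the BP waveform. Reconstruction starts after the
#' first N source samples: `values[k]` estimates the BP at source sample
#' `startIndex + k` (1-based), so the waveform has length L - N.
#'
#' @slot values numeric, mmHg.
#' @slot startIndex integer, number of skipped initial source samples (= N).
#' @slot fs sampling frequency, Hz.
#' @slot participantId character.
#'
#' @exportClass ReconstructedBP
setClass("ReconstructedBP",
  representation(
    values = "numeric",
    startIndex = "integer",
    fs = "numeric",
    participantId = "character"
  )
)

#' Bland-Altman agreement result
#'
#' Bias (mean of estimated minus reference), the standard deviation of the
#' paired differences (n - 1 denominator), and the 95% limits of agreement
#' `bias +/- 1.96 * sd`.
#'
#' @slot bias,sdDiff,loaLower,loaUpper numeric scalars, mmHg.
#' @slot n integer, number of pairs used.
#' @slot level `"window"` or `"recording"`.
#' @slot kind `"sbp"` or `"dbp"`.
#'
#' @exportClass BlandAltman
setClass("BlandAltman",
  representation(
    bias = "numeric",
    sdDiff = "numeric",
    loaLower = "numeric",
    loaUpper = "numeric",
    n = "integer",
    level = "character",
    kind = "character"
  )
)

setValidity("BlandAltman", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "need at least 2 pairs")
  tol <- 1e-8 * max(1, abs(object@bias))
  if (object@loaLower > object@bias + tol ||
    object@bias > object@loaUpper + tol)
    msg <- c(msg, "limits of agreement must bracket the bias")
  if (length(msg)) msg else TRUE
})
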