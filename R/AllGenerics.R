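#' @name bedpress-accessors
#' @title Accessors for bedpress classes
#' @description Accessor generics for the package's S4 containers.
#' @param object,x an object of the documented class.
#' @param ... further arguments for methods.
NULL

#' @rdname bedpress-accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))

#' @rdname bedpress-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname bedpress-accessors
#' @export
setGeneric("loadCells", function(object) standardGeneric("loadCells"))

#' @rdname bedpress-accessors
#' @export
setGeneric("bpWaveform", function(object) standardGeneric("bpWaveform"))

#' @rdname bedpress-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname bedpress-accessors
#' @export
setGeneric("recordingDuration",
  function(object) standardGeneric("recordingDuration"))

#' @rdname bedpress-accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))

#' @rdname bedpress-accessors
#' @export
setGeneric("windowLength", function(object) standardGeneric("windowLength"))

#' @rdname bedpress-accessors
#' @export
setGeneric("trainLoss", function(object) standardGeneric("trainLoss"))

#' @rdname bedpress-accessors
#' @export
setGeneric("valLoss", function(object) standardGeneric("valLoss"))

#' @rdname bedpress-accessors
#' @export
setGeneric("bestEpoch", function(object) standardGeneric("bestEpoch"))

#' @rdname bedpress-accessors
#' @export
setGeneric("agreementBias", function(object) standardGeneric("agreementBias"))

#' @rdname bedpress-accessors
#' @export
setGeneric("loaLimits", function(object) standardGeneric("loaLimits"))

#' Width of a Bland-Altman limits-of-agreement interval
#'
#' @param object a [BlandAltman-class] result, or a numeric vector of two
#'   limits `c(lower, upper)`.
#' @return The interval width `upper - lower`, in mmHg.
#' @examples
#' loaWidth(c(-13.09, 17.39))
#' @export
setGeneric("loaWidth", function(object) standardGeneric("loaWidth"))

## -- methods ---------------------------------------------------------------

#' @rdname bedpress-accessors
setMethod("participantId", "LoadCellRecording", function(object)
  object@participantId)

#' @rdname bedpress-accessors
setMethod("participantId", "WindowDataset", function(object)
  object@participantIds)

#' @rdname bedpress-accessors
setMethod("participantId", "ReconstructedBP", function(object)
  object@participantId)

#' @rdname bedpress-accessors
setMethod("samplingRate", "LoadCellRecording", function(object) object@fs)

#' @rdname bedpress-accessors
setMethod("samplingRate", "ReconstructedBP", function(object) object@fs)

#' @rdname bedpress-accessors
setMethod("loadCells", "LoadCellRecording", function(object)
  object@loadCells)

#' @rdname bedpress-accessors
setMethod("bpWaveform", "LoadCellRecording", function(object) object@bp)

#' @rdname bedpress-accessors
setMethod("bpWaveform", "ReconstructedBP", function(object) object@values)

#' @rdname bedpress-accessors
setMethod("nSamples", "LoadCellRecording", function(object)
  length(object@bp))

#' @rdname bedpress-accessors
setMethod("recordingDuration", "LoadCellRecording", function(object)
  length(object@bp) / object@fs)

#' @rdname bedpress-accessors
setMethod("nWindows", "WindowDataset", function(object)
  sum(vapply(object@signals, ncol, 0L)) -
    object@N * length(object@signals))

#' @rdname bedpress-accessors
setMethod("windowLength", "WindowDataset", function(object) object@N)

#' @rdname bedpress-accessors
setMethod("trainLoss", "TrainHistory", function(object) object@trainLoss)

#' @rdname bedpress-accessors
setMethod("valLoss", "TrainHistory", function(object) object@valLoss)

#' @rdname bedpress-accessors
setMethod("bestEpoch", "TrainHistory", function(object) object@bestEpoch)

#' @rdname bedpress-accessors
setMethod("agreementBias", "BlandAltman", function(object) object@bias)

#' @rdname bedpress-accessors
setMethod("loaLimits", "BlandAltman", function(object)
  c(lower = object@loaLower, upper = object@loaUpper))

#' @rdname loaWidth
#' @export
setMethod("loaWidth", "BlandAltman", function(object)
  object@loaUpper - object@loaLower)

#' @rdname loaWidth
#' @export
setMethod("loaWidth", "numeric", function(object) {
  if (length(object) != 2L)
    stop("expected a numeric vector c(lower, upper)")
  max(object) - min(object)
})

## -- show ------------------------------------------------------------------

setMethod("show", "LoadCellRecording", function(object) {
  cat(sprintf(
    "LoadCellRecording '%s': 4 load-cell channels + BP, %d samples @ %g Hz (%.1f s)\n",
    object@participantId, length(object@bp), object@fs,
    length(object@bp) / object@fs
  ))
  cat(sprintf(
    "  BP range: [%.1f, %.1f] mmHg\n",
    min(object@bp), max(object@bp)
  ))
})

setMethod("show", "WindowDataset", function(object) {
  cat(sprintf(
    "WindowDataset: %d windows of %d samples x 4 channels from %d recording(s)\n",
    nWindows(object), object@N, length(object@signals)
  ))
  cat("  participants:", paste(object@participantIds, collapse = ", "), "\n")
})

setMethod("show", "BPRegressor", function(object) {
  cfg <- object@config
  cat(sprintf(
    "BPRegressor: %d x LSTM(%d) -> dense(1), input %d steps x %d features\n",
    cfg$n_lstm_layers, cfg$lstm_units, cfg$input_steps, cfg$input_features
  ))
  cat(sprintf("  trainable parameters: %d\n", nTrainableParams(object)))
  cat(sprintf(
    "  target scaler: %s; input scaling: %s\n",
    if (length(object@scaler)) "min-max [0,1]" else "identity",
    object@inputScaling
  ))
})

setMethod("show", "TrainHistory", function(object) {
  cat(sprintf(
    "TrainHistory: %d epochs, best epoch %d (val MSE %.4g)\n",
    length(object@valLoss), object@bestEpoch,
    object@valLoss[object@bestEpoch]
  ))
})

setMethod("show", "ReconstructedBP", function(object) {
  cat(sprintf(
    "ReconstructedBP '%s': %d samples @ %g Hz, starts at source sample %d\n",
    object@participantId, length(object@values), object@fs,
    object@startIndex + 1L
  ))
})

setMethod("show", "BlandAltman", function(object) {
  cat(sprintf(
    "BlandAltman (%s-level %s, n = %d): bias %.2f mmHg, LoA [%.2f, %.2f] mmHg\n",
    object@level, toupper(object@kind), object@n, object@bias,
    object@loaLower, object@loaUpper
  ))
})
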