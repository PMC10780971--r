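## Waveform reconstruction metrics and Bland-Altman agreement analysis.

#' Waveform reconstruction metrics
#'
#' Mean squared error, mean absolute error and the coefficient of
#' determination R^2 = 1 - SSres / SStot (SStot about the reference mean)
#' between a reference and a reconstructed waveform of equal length.
#'
#' @param reference,reconstructed numeric vectors of equal length (the
#'   reference already truncated to drop its first N samples).
#' @param scale label recorded in the result: `"mmHg"` or `"normalized"`.
#' @return `list(mse, mae, r2, scale)` of class `WaveformMetrics`.
#' @examples
#' waveformMetrics(c(1, 2, 3), c(1, 2, 3))
#' @export
waveformMetrics <- function(reference, reconstructed, scale = "mmHg") {
  if (length(reference) != length(reconstructed))
    stop("reference and reconstructed lengths differ")
  if (length(reference) < 2) stop("need at least 2 samples")
  if (diff(range(reference)) == 0)
    stop("constant reference: R^2 undefined")
  err <- reconstructed - reference
  structure(
    list(
      mse = mean(err^2),
      mae = mean(abs(err)),
      r2 = 1 - sum(err^2) / sum((reference - mean(reference))^2),
      scale = scale
    ),
    class = "WaveformMetrics"
  )
}

#' Bland-Altman agreement between estimated and reference values
#'
#' Differences are estimated minus reference. The bias is their mean, the
#' limits of agreement are `bias +/- 1.96 * sd` with the sample (n - 1)
#' standard deviation. Pairs where either value is missing are dropped.
#'
#' @param estimated,reference paired numeric vectors.
#' @param level,kind labels stored in the result.
#' @return A [BlandAltman-class].
#' @examples
#' blandAltman(c(99, 100, 101), c(100, 100, 100))
#' @export
blandAltman <- function(estimated, reference, level = "window",
                        kind = "sbp") {
  if (length(estimated) != length(reference))
    stop("estimated and reference must be paired (equal length)")
  ok <- !(is.na(estimated) | is.na(reference))
  d <- estimated[ok] - reference[ok]
  if (length(d) < 2) stop("need at least 2 complete pairs")
  bias <- mean(d)
  s <- sd(d)
  new("BlandAltman",
    bias = bias, sdDiff = s,
    loaLower = bias - 1.96 * s, loaUpper = bias + 1.96 * s,
    n = length(d), level = level, kind = kind
  )
}

#' Evaluate a trained model on test recordings
#'
#' Runs the full evaluation pipeline on each test recording: reconstruct
#' the BP waveform, compute waveform metrics against the aligned reference
#' (its first N samples dropped), detect SBP/DBP events on both the
#' reconstructed and the reference waveform with the same detector, and
#' aggregate into five-second-window and recording-level estimates.
#' Window-level agreement pools index-aligned window pairs (both values
#' present) across all recordings; recording-level agreement pairs one
#' estimate per recording.
#'
#' @param model a trained [BPRegressor-class].
#' @param recordings list of test [LoadCellRecording-class] objects at
#'   100 Hz (participants disjoint from training).
#' @param window aggregation window, seconds.
#' @param sysGate,diaGate,refractory extrema-detection settings, see
#'   [detectEvents()].
#' @return A list:
#' \describe{
#'   \item{waveform}{per-recording data.frame of MSE, MAE, R^2 in mmHg
#'     (and on the normalized scale when the model carries a scaler).}
#'   \item{window_sbp, window_dbp}{pooled window-level
#'     [BlandAltman-class] results.}
#'   \item{recording_sbp, recording_dbp}{recording-level
#'     [BlandAltman-class] results (`NULL` when fewer than 2 recordings
#'     yield estimates).}
#'   \item{window_table, recording_table}{the paired estimates behind the
#'     agreement results.}
#' }
#' @export
evaluateCohort <- function(model, recordings, window = 5,
                           sysGate = c(100, 150), diaGate = c(60, 100),
                           refractory = 50L) {
  stopifnot(is(model, "BPRegressor"), length(recordings) >= 1)
  N <- model@config$input_steps
  hasScaler <- length(model@scaler) > 0

  wf <- list()
  winTabs <- list()
  recRows <- list()
  for (rec in recordings) {
    id <- participantId(rec)
    recon <- reconstructBP(model, rec)
    ref <- bpWaveform(rec)[(N + 1):nSamples(rec)]
    est <- bpWaveform(recon)
    m <- waveformMetrics(ref, est, scale = "mmHg")
    row <- data.frame(
      participant_id = id, mse = m$mse, mae = m$mae, r2 = m$r2
    )
    if (hasScaler) {
      mn <- waveformMetrics(
        scaleTargets(model@scaler, ref), scaleTargets(model@scaler, est),
        scale = "normalized"
      )
      row$mse_norm <- mn$mse
      row$mae_norm <- mn$mae
    }
    wf[[id]] <- row

    dur <- length(ref) / samplingRate(rec)
    evEst <- detectEvents(est, samplingRate(rec), sysGate, diaGate, refractory)
    evRef <- detectEvents(ref, samplingRate(rec), sysGate, diaGate, refractory)
    wEst <- windowEstimates(evEst, dur, window)
    wRef <- windowEstimates(evRef, dur, window)
    winTabs[[id]] <- data.frame(
      participant_id = id, window_start = wEst$window_start,
      sbp_est = wEst$sbp, sbp_ref = wRef$sbp,
      dbp_est = wEst$dbp, dbp_ref = wRef$dbp
    )

    recEst <- tryCatch(recordingEstimate(wEst), error = function(e) NULL)
    recRef <- tryCatch(recordingEstimate(wRef), error = function(e) NULL)
    recRows[[id]] <- data.frame(
      participant_id = id,
      sbp_est = if (is.null(recEst)) NA_real_ else recEst$sbp_mean,
      sbp_ref = if (is.null(recRef)) NA_real_ else recRef$sbp_mean,
      dbp_est = if (is.null(recEst)) NA_real_ else recEst$dbp_mean,
      dbp_ref = if (is.null(recRef)) NA_real_ else recRef$dbp_mean
    )
  }
  winTab <- do.call(rbind, winTabs)
  recTab <- do.call(rbind, recRows)
  rownames(winTab) <- rownames(recTab) <- NULL

  baOrNull <- function(est, ref, level, kind) {
    if (sum(!(is.na(est) | is.na(ref))) < 2) return(NULL)
    blandAltman(est, ref, level = level, kind = kind)
  }
  list(
    waveform = do.call(rbind, c(wf, list(make.row.names = FALSE))),
    window_sbp = baOrNull(winTab$sbp_est, winTab$sbp_ref, "window", "sbp"),
    window_dbp = baOrNull(winTab$dbp_est, winTab$dbp_ref, "window", "dbp"),
    recording_sbp = baOrNull(recTab$sbp_est, recTab$sbp_ref, "recording", "sbp"),
    recording_dbp = baOrNull(recTab$dbp_est, recTab$dbp_ref, "recording", "dbp"),
    window_table = winTab,
    recording_table = recTab
  )
}
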