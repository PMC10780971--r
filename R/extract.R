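## SBP/DBP extraction: derivative zero-crossing extrema detection with
## amplitude gates and refractory separation, then 5-s-window and
## per-recording aggregation.

#' Detect systolic and diastolic events in a BP waveform
#'
#' Works on the first difference `d[i] = x[i+1] - x[i]`. A negative-going
#' zero-crossing (`d[i-1] > 0` and `d[i] <= 0`) proposes a local maximum
#' at sample `i`; a positive-going one (`d[i-1] < 0` and `d[i] >= 0`)
#' proposes a local minimum (flat tops resolve to their first sample).
#' Proposals outside the amplitude gate of their kind are discarded.
#' Surviving same-kind events closer than `refractory` samples are then
#' thinned greedily by amplitude priority — the larger maximum (smaller
#' minimum) wins, ties going to the earlier sample — so that retained
#' events are separated by at least `refractory` samples.
#'
#' @param x numeric BP waveform, mmHg.
#' @param fs sampling frequency, Hz.
#' @param sysGate,diaGate inclusive amplitude gates, mmHg.
#' @param refractory minimum separation between same-kind events, samples
#'   (50 samples = 0.5 s at 100 Hz).
#' @param applyRefractory set `FALSE` to return all gated proposals.
#' @return `data.frame(index, time, amplitude, kind)` sorted by index;
#'   `index` is 1-based, `time = (index - 1) / fs` seconds, `kind` is
#'   `"systolic"` or `"diastolic"`.
#' @examples
#' t <- seq(0, 5, by = 0.01)
#' ev <- detectEvents(100 + 20 * sin(2 * pi * 1.2 * t))
#' table(ev$kind)
#' @export
detectEvents <- function(x, fs = 100, sysGate = c(100, 150),
                         diaGate = c(60, 100), refractory = 50L,
                         applyRefractory = TRUE) {
  if (length(x) < 3) stop("waveform too short (need >= 3 samples)")
  d <- diff(x)
  i <- 2:(length(x) - 1)
  isMax <- d[i - 1] > 0 & d[i] <= 0
  isMin <- d[i - 1] < 0 & d[i] >= 0

  gate <- function(idx, g) idx[x[idx] >= g[1] & x[idx] <= g[2]]
  sys <- gate(i[isMax], sysGate)
  dia <- gate(i[isMin], diaGate)

  if (applyRefractory) {
    sys <- thinRefractory(sys, x[sys], refractory, decreasing = TRUE)
    dia <- thinRefractory(dia, x[dia], refractory, decreasing = FALSE)
  }
  ev <- data.frame(
    index = c(sys, dia),
    amplitude = c(x[sys], x[dia]),
    kind = rep(c("systolic", "diastolic"), c(length(sys), length(dia))),
    stringsAsFactors = FALSE
  )
  ev <- ev[order(ev$index), , drop = FALSE]
  ev$time <- (ev$index - 1) / fs
  rownames(ev) <- NULL
  ev[, c("index", "time", "amplitude", "kind")]
}

## Greedy amplitude-priority thinning: visit candidates from most to least
## extreme (ties: earlier sample first) and keep each one that is at least
## `sep` samples away from every already-kept event.
thinRefractory <- function(idx, amp, sep, decreasing) {
  if (length(idx) <= 1) return(idx)
  ord <- order(if (decreasing) -amp else amp, idx)
  kept <- integer(0)
  for (j in ord) {
    if (!length(kept) || all(abs(idx[j] - kept) >= sep))
      kept <- c(kept, idx[j])
  }
  sort(kept)
}

#' Aggregate events into consecutive five-second windows
#'
#' Tiles `[0, duration)` into non-overlapping windows of `window` seconds
#' (half-open `[start, start + window)`); a final partial window is
#' included. Each window's SBP (DBP) is the mean amplitude of the systolic
#' (diastolic) events whose time falls inside it; windows without events
#' of a kind get `NA`, never zero.
#'
#' @param events data.frame from [detectEvents()].
#' @param duration waveform duration, seconds.
#' @param window window length, seconds.
#' @return `data.frame(window_start, sbp, dbp, n_sys_events,
#'   n_dia_events)`.
#' @export
windowEstimates <- function(events, duration, window = 5) {
  if (window <= 0) stop("window must be positive")
  starts <- seq(0, duration - 1e-9, by = window)
  agg <- function(kind, s) {
    sel <- events$kind == kind & events$time >= s & events$time < s + window
    a <- events$amplitude[sel]
    c(if (length(a)) mean(a) else NA_real_, length(a))
  }
  out <- t(vapply(starts, function(s) c(agg("systolic", s), agg("diastolic", s)),
    numeric(4)))
  data.frame(
    window_start = starts, sbp = out[, 1], dbp = out[, 3],
    n_sys_events = as.integer(out[, 2]), n_dia_events = as.integer(out[, 4])
  )
}

#' Per-recording SBP/DBP estimate
#'
#' The unweighted mean of the per-window values, skipping windows without
#' a value of that kind.
#'
#' @param wins data.frame from [windowEstimates()].
#' @return `list(sbp_mean, dbp_mean, n_windows_sbp, n_windows_dbp)`.
#' @export
recordingEstimate <- function(wins) {
  nS <- sum(!is.na(wins$sbp))
  nD <- sum(!is.na(wins$dbp))
  if (nS == 0 && nD == 0)
    stop("no usable windows: no systolic or diastolic events detected")
  list(
    sbp_mean = if (nS) mean(wins$sbp, na.rm = TRUE) else NA_real_,
    dbp_mean = if (nD) mean(wins$dbp, na.rm = TRUE) else NA_real_,
    n_windows_sbp = nS, n_windows_dbp = nD
  )
}

#' Extract window and recording estimates from a waveform
#'
#' Convenience composition of [detectEvents()], [windowEstimates()] and
#' [recordingEstimate()].
#'
#' @param x numeric BP waveform, mmHg.
#' @inheritParams detectEvents
#' @param window window length, seconds.
#' @return `list(events =, windows =, recording =)`.
#' @export
extractBP <- function(x, fs = 100, sysGate = c(100, 150),
                      diaGate = c(60, 100), refractory = 50L, window = 5) {
  ev <- detectEvents(x, fs, sysGate, diaGate, refractory)
  wins <- windowEstimates(ev, duration = length(x) / fs, window = window)
  list(events = ev, windows = wins, recording = recordingEstimate(wins))
}
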