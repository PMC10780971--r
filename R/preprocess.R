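## Signal conditioning: zero-phase Butterworth band-pass of the load-cell
## channels and decimation of all channels to the 100 Hz analysis rate.

#' Band-pass filter specification
#'
#' @param low_cut,high_cut band edges, Hz. Defaults 0.05 and 35 Hz: the
#'   band keeps the cardiac and respiratory content of the BCG while
#'   removing the static load offset and mains-range noise.
#' @param order Butterworth order of each cascade section.
#' @return A validated list of class `FilterSpec`.
#' @examples
#' spec <- filterSpec()
#' y <- bandpass(sin(2 * pi * 1 * seq(0, 10, by = 0.01)), 100, spec)
#' @export
filterSpec <- function(low_cut = 0.05, high_cut = 35, order = 4L) {
  if (!(low_cut > 0 && low_cut < high_cut))
    stop("need 0 < low_cut < high_cut")
  if (order < 1) stop("order must be >= 1")
  structure(
    list(low_cut = low_cut, high_cut = high_cut, order = as.integer(order),
      design = "butterworth"),
    class = "FilterSpec"
  )
}

## Odd-reflection padding: extends the signal antisymmetrically about its
## end points, which suppresses filtfilt edge transients (the 0.05 Hz
## high-pass has a multi-second impulse response).
padReflectOdd <- function(x, P) {
  L <- length(x)
  P <- min(P, L - 1)
  front <- 2 * x[1] - x[(P + 1):2]
  back <- 2 * x[L] - x[(L - 1):(L - P)]
  list(x = c(front, x, back), P = P)
}

zeroPhase <- function(filt, x, P) {
  p <- padReflectOdd(x, P)
  y <- signal::filtfilt(filt, p$x)
  y[(p$P + 1):(p$P + length(x))]
}

#' Zero-phase Butterworth band-pass
#'
#' Realized as a cascade of a high-pass and a low-pass Butterworth section
#' (each of `spec$order`), applied forward-backward for zero phase so that
#' downstream extrema timing is unaffected. The signal mean is removed
#' first and the ends are odd-reflection padded, which keeps the very-low
#' cut-off (0.05 Hz) numerically clean: a constant input maps to zero.
#'
#' @param x numeric signal.
#' @param fs sampling frequency, Hz.
#' @param spec a [filterSpec()].
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, spec = filterSpec()) {
  stopifnot(inherits(spec, "FilterSpec"))
  if (spec$high_cut >= fs / 2)
    stop("high_cut must be below the Nyquist frequency")
  if (length(x) <= 3 * spec$order)
    stop("signal too short for filter order")
  hp <- signal::butter(spec$order, spec$low_cut / (fs / 2), type = "high")
  lp <- signal::butter(spec$order, spec$high_cut / (fs / 2), type = "low")
  P <- min(length(x) - 1, round(3 * fs / spec$low_cut))
  y <- x - mean(x)
  y <- zeroPhase(hp, y, P)
  zeroPhase(lp, y, P)
}

#' Decimate a signal to 100 Hz
#'
#' Identity at 100 Hz. From 1000 Hz: the length is truncated to a multiple
#' of 10, an 8th-order zero-phase Butterworth anti-alias low-pass at 40 Hz
#' is applied, and every 10th sample is kept, giving `floor(L / 10)`
#' samples.
#'
#' @param x numeric signal.
#' @param fs_in input sampling frequency, 100 or 1000 Hz.
#' @return The decimated signal.
#' @export
decimateTo100Hz <- function(x, fs_in) {
  if (fs_in == 100) return(x)
  if (fs_in != 1000) stop("fs_in must be 100 or 1000 Hz")
  Lt <- 10 * (length(x) %/% 10)
  if (Lt < 100) stop("signal too short to decimate")
  x <- x[seq_len(Lt)]
  aa <- signal::butter(8, 40 / (fs_in / 2), type = "low")
  y <- zeroPhase(aa, x - mean(x), min(Lt - 1, 2000)) + mean(x)
  y[seq(1, Lt, by = 10)]
}

#' Condition a recording for analysis
#'
#' Band-passes each load-cell channel (the BP channel is left unfiltered:
#' it is a calibrated pressure signal whose absolute level must be
#' preserved), then decimates all five channels to 100 Hz.
#'
#' @param rec a [LoadCellRecording-class] at 100 or 1000 Hz.
#' @param spec a [filterSpec()].
#' @return A [LoadCellRecording-class] at 100 Hz.
#' @examples
#' rec <- simulateParticipant(participantParams(seed = 2), duration = 10)
#' pre <- preprocessRecording(rec)
#' @export
preprocessRecording <- function(rec, spec = filterSpec()) {
  stopifnot(is(rec, "LoadCellRecording"))
  lc <- t(apply(rec@loadCells, 1, bandpass, fs = rec@fs, spec = spec))
  lc <- t(apply(lc, 1, decimateTo100Hz, fs_in = rec@fs))
  bp <- decimateTo100Hz(rec@bp, rec@fs)
  loadCellRecording(rec@participantId, 100, lc, bp)
}
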