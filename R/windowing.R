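## Sliding-window dataset construction and participant-level partitioning.

#' Build the sliding-window regression dataset
#'
#' For a 100 Hz recording of length L, forms one training pair per target
#' sample `t` in `N+1 .. L` (1-based): the input is the strictly causal
#' window of the N preceding load-cell samples (4 channels), the target is
#' the BP sample at `t`. Successive windows are shifted by one sample, so
#' the dataset reconstructs the whole waveform except the first N samples.
#'
#' @param rec a [LoadCellRecording-class] at 100 Hz.
#' @param N window length in samples (default 50, i.e. 0.5 s at 100 Hz).
#' @return A [WindowDataset-class].
#' @examples
#' rec <- simulateParticipant(participantParams(seed = 1), duration = 5)
#' ds <- buildWindows(rec)
#' nWindows(ds)  # 500 - 50
#' @export
buildWindows <- function(rec, N = 50L) {
  stopifnot(is(rec, "LoadCellRecording"))
  if (rec@fs != 100) stop("buildWindows expects a 100 Hz recording")
  N <- as.integer(N)
  L <- nSamples(rec)
  if (L <= N) stop("recording shorter than N + 1 samples")
  new("WindowDataset",
    signals = list(rec@loadCells),
    targets = list(rec@bp[(N + 1):L]),
    participantIds = rec@participantId,
    N = N
  )
}

#' Concatenate window datasets
#'
#' Windows never span recording boundaries: datasets built per recording
#' are concatenated afterwards.
#'
#' @param ... [WindowDataset-class] objects (or one list of them).
#' @return A single [WindowDataset-class].
#' @export
concatWindows <- function(...) {
  dss <- list(...)
  if (length(dss) == 1L && is.list(dss[[1]]) && !is(dss[[1]], "WindowDataset"))
    dss <- dss[[1]]
  if (!all(vapply(dss, is, TRUE, "WindowDataset")))
    stop("all arguments must be WindowDataset objects")
  Ns <- vapply(dss, function(d) d@N, 0L)
  if (length(unique(Ns)) != 1L) stop("window lengths differ")
  new("WindowDataset",
    signals = do.call(c, lapply(dss, function(d) d@signals)),
    targets = do.call(c, lapply(dss, function(d) d@targets)),
    participantIds = do.call(c, lapply(dss, function(d) d@participantIds)),
    N = Ns[1]
  )
}

#' Materialize one input window
#'
#' @param ds a [WindowDataset-class].
#' @param i window index in `1 .. nWindows(ds)`, in dataset order.
#' @return A 4 x N matrix: channels LC0..LC3 in rows, the N consecutive
#'   source samples in columns.
#' @export
windowInput <- function(ds, i) {
  stopifnot(is(ds, "WindowDataset"))
  counts <- vapply(ds@signals, ncol, 0L) - ds@N
  if (i < 1 || i > sum(counts)) stop("window index out of range")
  r <- findInterval(i - 1, cumsum(c(0, counts)), rightmost.closed = FALSE)
  k <- i - c(0, cumsum(counts))[r]
  ds@signals[[r]][, k:(k + ds@N - 1), drop = FALSE]
}

#' Window targets in dataset order
#'
#' @param ds a [WindowDataset-class].
#' @return Numeric vector of BP targets (mmHg), one per window.
#' @export
windowTargets <- function(ds) {
  stopifnot(is(ds, "WindowDataset"))
  unlist(ds@targets, use.names = FALSE)
}

#' Target sample indices per source recording
#'
#' @param ds a [WindowDataset-class].
#' @return A list with, per source recording, the 1-based indices
#'   `(N+1) .. L` of the predicted BP samples.
#' @export
targetIndices <- function(ds) {
  stopifnot(is(ds, "WindowDataset"))
  lapply(ds@signals, function(s) (ds@N + 1L):ncol(s))
}

#' Partition participant ids into train / validation / test sets
#'
#' Participant-disjoint splitting: the ids are randomly permuted under the
#' given seed and divided by rounded fractions, so all windows of a
#' participant land in exactly one set.
#'
#' @param ids character vector of participant ids (>= 3).
#' @param fractions numeric length 3 summing to 1; default the 22/38,
#'   6/38, 10/38 train/validation/test proportions.
#' @param seed integer seed for the permutation.
#' @return `list(train =, val =, test =)` of disjoint id vectors.
#' @examples
#' partitionParticipants(sprintf("P%02d", 1:38), seed = 7)
#' @export
partitionParticipants <- function(ids,
                                  fractions = c(22, 6, 10) / 38,
                                  seed = 1L) {
  n <- length(ids)
  if (n < 3) stop("need at least 3 participant ids")
  if (length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be 3 values summing to 1")
  perm <- withSeed(seed, sample(ids))
  nTrain <- round(fractions[1] * n)
  nVal <- round(fractions[2] * n)
  nTest <- n - nTrain - nVal
  if (min(nTrain, nVal, nTest) < 1) stop("a split would be empty")
  list(
    train = perm[seq_len(nTrain)],
    val = perm[nTrain + seq_len(nVal)],
    test = perm[nTrain + nVal + seq_len(nTest)]
  )
}

#' Build windows for a set of recordings
#'
#' Convenience wrapper: [buildWindows()] per recording, then
#' [concatWindows()].
#'
#' @param recordings list of [LoadCellRecording-class] at 100 Hz.
#' @param N window length in samples.
#' @return A [WindowDataset-class].
#' @export
buildWindowsCohort <- function(recordings, N = 50L) {
  concatWindows(lapply(recordings, buildWindows, N = N))
}
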