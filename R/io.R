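## Columnar CSV reader/writer for synchronized recordings.
## Layout: header `t,lc0,lc1,lc2,lc3,bp`, one row per sample, t in seconds
## with 6-decimal fixed point.

#' Write a recording to CSV
#'
#' @param rec a [LoadCellRecording-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @examples
#' rec <- simulateParticipant(participantParams(seed = 1), duration = 2)
#' f <- tempfile(fileext = ".csv")
#' writeRecordingCSV(rec, f)
#' rec2 <- readRecordingCSV(f, participantId = participantId(rec))
#' @export
writeRecordingCSV <- function(rec, path) {
  stopifnot(is(rec, "LoadCellRecording"))
  L <- nSamples(rec)
  t <- (seq_len(L) - 1) / rec@fs
  lines <- sprintf(
    "%.6f,%.6f,%.6f,%.6f,%.6f,%.6f",
    t, rec@loadCells[1, ], rec@loadCells[2, ], rec@loadCells[3, ],
    rec@loadCells[4, ], rec@bp
  )
  writeLines(c("t,lc0,lc1,lc2,lc3,bp", lines), path)
  invisible(path)
}

#' Read a recording from CSV
#'
#' The sampling rate is recovered from the median spacing of the time
#' column and rounded to the nearest Hz.
#'
#' @param path CSV file with columns `t,lc0,lc1,lc2,lc3,bp`.
#' @param participantId identifier to attach; defaults to the file name
#'   without extension.
#' @return A [LoadCellRecording-class].
#' @export
readRecordingCSV <- function(path, participantId = NULL) {
  df <- read.csv(path)
  need <- c("t", "lc0", "lc1", "lc2", "lc3", "bp")
  if (!all(need %in% names(df)))
    stop("CSV must have columns ", paste(need, collapse = ","))
  if (nrow(df) < 2) stop("recording too short")
  fs <- round(1 / stats::median(diff(df$t)))
  if (is.null(participantId))
    participantId <- sub("\\.[^.]*$", "", basename(path))
  loadCellRecording(
    participantId, fs,
    t(as.matrix(df[, c("lc0", "lc1", "lc2", "lc3")])), df$bp
  )
}

#' Write a cohort of recordings to a directory
#'
#' One CSV per recording, named `<participantId>.csv`.
#'
#' @param cohort list of [LoadCellRecording-class] objects.
#' @param dir output directory (created if missing).
#' @return The file paths, invisibly.
#' @export
writeCohortCSV <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(r)
    writeRecordingCSV(r, file.path(dir, paste0(participantId(r), ".csv"))),
    "")
  invisible(paths)
}

#' Read all recording CSVs in a directory
#'
#' @param dir directory containing `*.csv` recordings.
#' @return Named list of [LoadCellRecording-class] objects.
#' @export
readCohortCSV <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no .csv recordings in ", dir)
  cohort <- lapply(files, readRecordingCSV)
  names(cohort) <- vapply(cohort, participantId, "")
  cohort
}
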