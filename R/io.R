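# File interchange: multi-page 16-bit grayscale TIFF with a JSON metadata
# sidecar for videos; two-column CSV for ECG; one-column CSV for R-peaks;
# JSON for schedules and QC records.

#' Write a video as multi-page TIFF with JSON sidecar
#'
#' One 16-bit grayscale page per frame; 10-bit counts are stored in the
#' 16-bit container (values <= 1023). The sidecar
#' \code{<file>.json} records frame rate, pixel pitch, t0, bit depth and
#' any extra metadata supplied.
#'
#' @param video a \linkS4class{VideoRecording}.
#' @param path output TIFF path.
#' @param metadata named list merged into the sidecar.
#' @return invisibly, the sidecar path.
#' @export
writeVideoTIFF <- function(video, path, metadata = list()) {
  X <- videoFrames(video)
  maxCount <- 2^video@bitDepth - 1
  if (max(X) > maxCount)
    stop(sprintf("pixel values exceed the %d-bit range", video@bitDepth))
  pages <- lapply(seq_len(dim(X)[3]), function(i)
    pmax(X[, , i], 0) / 65535)           # tiff writes [0,1] -> 16-bit
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- paste0(path, ".json")
  meta <- c(list(frame_rate_hz = frameRate(video),
                 pixel_pitch_um = pixelPitch(video),
                 t0 = video@t0, bit_depth = video@bitDepth,
                 n_frames = dim(X)[3], height_px = dim(X)[1],
                 width_px = dim(X)[2]),
            metadata)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a video from multi-page TIFF with JSON sidecar
#'
#' @param path TIFF path written by \code{\link{writeVideoTIFF}}.
#' @return a \linkS4class{VideoRecording}.
#' @export
readVideoTIFF <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  X <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) X[, , i] <- pages[[i]] * 65535
  VideoRecording(X, frameRate = meta$frame_rate_hz,
                 pixelPitchUm = meta$pixel_pitch_um,
                 bitDepth = as.integer(meta$bit_depth), t0 = meta$t0)
}

#' Write / read an ECG trace as two-column CSV (time_s, mV)
#'
#' @param ecg an \linkS4class{ECGTrace}.
#' @param path CSV path.
#' @return \code{writeECGCsv}: invisibly, the path. \code{readECGCsv}: an
#'   \linkS4class{ECGTrace} (the sampling rate is inferred from the time
#'   column).
#' @export
writeECGCsv <- function(ecg, path) {
  t <- ecg@t0 + (seq_along(ecg@signalMv) - 1) / ecg@rateHz
  utils::write.csv(data.frame(time_s = t, mV = ecg@signalMv), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeECGCsv
#' @export
readECGCsv <- function(path) {
  df <- utils::read.csv(path)
  rate <- 1 / median(diff(df$time_s))
  ECGTrace(df$mV, rateHz = rate, t0 = df$time_s[1])
}

#' Write / read R-peak times as one-column CSV
#'
#' @param rpeaks an \linkS4class{RPeakSeries}.
#' @param path CSV path.
#' @return \code{writeRPeaksCsv}: invisibly, the path;
#'   \code{readRPeaksCsv}: an \linkS4class{RPeakSeries} with source
#'   "provided" (monotonicity is checked by the class validity).
#' @export
writeRPeaksCsv <- function(rpeaks, path) {
  utils::write.csv(data.frame(time_s = peakTimes(rpeaks)), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeRPeaksCsv
#' @export
readRPeaksCsv <- function(path) {
  RPeakSeries(utils::read.csv(path)$time_s, source = "provided")
}

#' Dump a motion field as CSV
#'
#' Long format: frame, seg_row, seg_col, dx, dy, flagged.
#'
#' @param field a \linkS4class{MotionField}.
#' @param path CSV path.
#' @return invisibly, the path.
#' @export
writeMotionFieldCsv <- function(field, path) {
  d <- dim(field@dx)
  df <- data.frame(
    frame = rep(seq_len(d[3]), each = d[1] * d[2]),
    seg_row = rep(seq_len(d[1]), times = d[2] * d[3]),
    seg_col = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    dx = as.vector(field@dx), dy = as.vector(field@dy),
    flagged = as.vector(field@flagged))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write an experiment schedule as JSON
#'
#' @param dataset an \linkS4class{ExperimentDataset}.
#' @param path JSON path.
#' @return invisibly, the path.
#' @export
writeScheduleJSON <- function(dataset, path) {
  sch <- trialSchedule(dataset)
  sch$stage <- as.character(sch$stage)
  jsonlite::write_json(sch, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
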