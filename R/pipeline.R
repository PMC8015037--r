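# End-to-end single-trial analysis: motion compensation -> cardiac gating ->
# APC map and big-ROI selection -> normalized APC/OIS traces -> integral
# metrics and the OIS contact gate.

#' APC time series averaged over one big ROI
#'
#' Computes the APC series of every 3 x 3 px tile inside a 27 x 27 px
#' window (10-cycle ensemble windows sliding by one cycle) and averages the
#' per-tile APC values, the convention used for the big-ROI response traces.
#'
#' @param video a motion-compensated \linkS4class{VideoRecording}.
#' @param rpeaks an \linkS4class{RPeakSeries}.
#' @param origin (row, col) of the big ROI's top-left pixel, 1-based.
#' @param roiPx big-ROI side, pixels.
#' @param tilePx small-ROI side, pixels.
#' @param nCycles cycles per ensemble window.
#' @param stepCycles window step in cycles.
#' @param phasePoints phase samples per cycle.
#' @param method cycle resampling kernel, "cubic" or "linear".
#' @return data.frame (t, apc) with APC in percent.
#' @export
apcRoiSeries <- function(video, rpeaks, origin, roiPx = 27L, tilePx = 3L,
                         nCycles = 10L, stepCycles = 1L, phasePoints = 50L,
                         method = c("cubic", "linear")) {
  method <- match.arg(method)
  X <- videoFrames(video)
  d <- dim(X)
  r0 <- as.integer(origin[1]); c0 <- as.integer(origin[2])
  if (r0 < 1L || c0 < 1L || r0 + roiPx - 1L > d[1] || c0 + roiPx - 1L > d[2])
    stop("big ROI must lie fully inside the frame")
  fps <- frameRate(video)
  tF <- frameTimes(video)
  rt <- peakTimes(rpeaks)
  if (length(rt) < nCycles + 1L) stop("not enough cardiac cycles")

  nTr <- roiPx %/% tilePx; nTc <- nTr
  sub <- X[r0:(r0 + nTr * tilePx - 1L), c0:(c0 + nTc * tilePx - 1L), ,
           drop = FALSE]
  tileIdx <- as.vector(outer(rep(seq_len(nTr), each = tilePx),
                             (rep(seq_len(nTc), each = tilePx) - 1L) * nTr,
                             "+"))
  nTiles <- nTr * nTc
  M <- matrix(0, nTiles, d[3])
  for (i in seq_len(d[3]))
    M[, i] <- rowsum(as.vector(sub[, , i]), tileIdx, reorder = TRUE)[, 1] /
      (tilePx * tilePx)
  w <- oddWindowFrames(median(diff(rt)), fps)
  DC <- t(centeredMAMat(t(M), w))
  badTile <- apply(DC <= 0, 1L, any)
  DC[DC <= 0] <- NA_real_
  AC <- (M - DC) / DC

  phase <- (seq_len(phasePoints) - 1) / phasePoints
  starts <- seq.int(1L, length(rt) - nCycles, by = stepCycles)
  tsOut <- apcOut <- numeric(length(starts))
  for (si in seq_along(starts)) {
    s <- starts[si]
    acc <- matrix(0, nTiles, phasePoints)
    for (k in seq_len(nCycles)) {
      i <- s + k - 1L
      ts <- rt[i] + phase * (rt[i + 1L] - rt[i])
      acc <- acc + resampleUniform(AC, tF[1], 1 / fps, ts, method)
    }
    pulse <- acc / nCycles
    apcTile <- 100 * (apply(pulse, 1L, max) - apply(pulse, 1L, min))
    apcOut[si] <- mean(apcTile[!badTile])
    tsOut[si] <- (rt[s] + rt[s + nCycles]) / 2
  }
  data.frame(t = tsOut, apc = apcOut)
}

#' Analyze one stimulation trial from video and ECG
#'
#' The full processing chain: segment-wise motion compensation, R-peak
#' gating (detected from the ECG unless an \linkS4class{RPeakSeries} is
#' provided), APC map at the 10th second of stimulation, greedy big-ROI
#' selection near the electrodes, APC and OIS traces averaged over the two
#' representative ROIs, pre-stimulation normalization, integral metrics and
#' the 7% OIS contact gate.
#'
#' @param video the raw \linkS4class{VideoRecording}.
#' @param ecg an \linkS4class{ECGTrace}, or NULL when \code{rpeaks} given.
#' @param protocol the \linkS4class{TrialProtocol}.
#' @param electrodeXY 2 x 2 matrix of electrode (row, col) positions.
#' @param rpeaks optional externally provided \linkS4class{RPeakSeries}
#'   (takes precedence over detection).
#' @param kRois number of big ROIs to select.
#' @param bigRoiPx big-ROI side, pixels.
#' @param compensateMotion run motion compensation (TRUE).
#' @param qcThresholdPercent OIS gate threshold.
#' @param trialId identifier for reporting.
#' @return list of class "trialAnalysis": rpeaks, motion (field), map
#'   (\linkS4class{APCMap}), rois (\linkS4class{BigROISelection}),
#'   apcTrace and oisTrace (\linkS4class{NormalizedTrace}), qc, and
#'   metrics (data.frame with the integral metrics per parameter).
#' @export
analyzeTrial <- function(video, ecg = NULL, protocol = TrialProtocol(),
                         electrodeXY, rpeaks = NULL, kRois = 6L,
                         bigRoiPx = 27L, compensateMotion = TRUE,
                         qcThresholdPercent = 7, trialId = "trial") {
  if (is.null(rpeaks)) {
    if (is.null(ecg)) stop("either an ECG or an R-peak series is required")
    rpeaks <- detectRPeaks(ecg)
  }
  if (length(peakTimes(rpeaks)) < 11L)
    stop("fewer than 11 R-peaks: cannot build a 10-cycle window")

  field <- NULL
  if (compensateMotion) {
    mc <- motionCompensate(video, rpeaks = rpeaks)
    videoMc <- mc$video; field <- mc$field
  } else videoMc <- video

  mapTime <- protocol@preS + min(10, protocol@stimS / 2 + 5)
  map <- apcMap(videoMc, rpeaks, atTimeS = mapTime)
  rois <- selectBigRois(map, electrodeXY, k = kRois, roiPx = bigRoiPx)
  repIdx <- which(representativeRois(rois))

  # APC trace: mean over the two representative ROIs
  apcs <- lapply(repIdx, function(i)
    apcRoiSeries(videoMc, rpeaks, roiOrigins(rois)[i, ], roiPx = bigRoiPx))
  apcRaw <- data.frame(t = apcs[[1]]$t,
                       v = rowMeans(sapply(apcs, `[[`, "apc")))
  apcTrace <- normalizeTrace(apcRaw$t, apcRaw$v, "APC", protocol)

  # OIS trace on the DC-filtered compensated sequence, same two ROIs
  videoDc <- dcFilterVideo(videoMc, rpeaks)
  oisTc <- oisTimecourse(videoDc, roiOrigins(rois)[repIdx, , drop = FALSE],
                         protocol, roiPx = bigRoiPx)
  qc <- qcGate(oisTc, protocol, thresholdPercent = qcThresholdPercent,
               trialId = trialId)
  oisAgg <- stats::aggregate(ois ~ t, data = oisTc, FUN = mean)
  oisTrace <- normalizeTrace(oisAgg$t, 100 + oisAgg$ois, "OIS", protocol)

  metrics <- do.call(rbind, lapply(list(apcTrace, oisTrace), function(nt) {
    ia <- integralAdaptive(nt, protocol)
    data.frame(parameter = nt@parameter,
               integral = integralStim(nt, protocol),
               integralAdaptive = ia$integral, endS = ia$endS,
               truncated = ia$truncated, preStimSD = nt@preStimSD)
  }))

  structure(list(trialId = trialId, rpeaks = rpeaks, motion = field,
                 map = map, rois = rois, apcTrace = apcTrace,
                 oisTrace = oisTrace, qc = qc, metrics = metrics),
            class = "trialAnalysis")
}

#' @export
print.trialAnalysis <- function(x, ...) {
  cat(sprintf("Trial analysis '%s':\n", x$trialId))
  show(x$rois)
  print(x$qc)
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}
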