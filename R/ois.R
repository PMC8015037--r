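# Optical intrinsic signals: relative intensity decrease against the first
# pre-stimulation frame, computed on the DC-filtered (heartbeat-free),
# motion-compensated sequence; plus the 7% stimulation-contact QC gate.

#' DC-filter a video (remove the cardiac component)
#'
#' Per-pixel centered moving average over one median cardiac cycle (odd
#' frame count). Heartbeat modulation is noise for OIS purposes and a
#' cycle-length window nulls it by construction.
#'
#' @param video a \linkS4class{VideoRecording}.
#' @param rpeaks an \linkS4class{RPeakSeries} (sets the window length).
#' @return a \linkS4class{VideoRecording} of DC frames.
#' @export
dcFilterVideo <- function(video, rpeaks) {
  X <- videoFrames(video)
  d <- dim(X)
  w <- oddWindowFrames(median(diff(peakTimes(rpeaks))), frameRate(video))
  Xm <- matrix(X, nrow = d[1] * d[2])       # pixels x time
  DC <- t(centeredMAMat(t(Xm), w))
  VideoRecording(array(DC, dim = d), frameRate = frameRate(video),
                 pixelPitchUm = pixelPitch(video), bitDepth = video@bitDepth,
                 t0 = video@t0)
}

#' Per-pixel OIS map of one frame
#'
#' OIS_i(x, y) = (I0(x, y) - I_i(x, y)) / I0(x, y) x 100 percent, with I0
#' the first frame of the trial's pre-stimulation phase (or
#' \code{referenceIndex}). Positive OIS = darker tissue = more blood volume
#' under green light. Pixels with I0 <= \code{epsCounts} are masked.
#' Intended to run on the DC-filtered, motion-compensated sequence; any
#' sequence is accepted.
#'
#' @param video a \linkS4class{VideoRecording} (DC-filtered for the standard
#'   analysis).
#' @param i frame index to map.
#' @param referenceIndex index of I0 (1 = first frame).
#' @param epsCounts mask threshold for I0, counts.
#' @return an \linkS4class{OISMap}.
#' @export
oisFrame <- function(video, i, referenceIndex = 1L, epsCounts = 1) {
  X <- videoFrames(video)
  nT <- dim(X)[3]
  i <- as.integer(i); referenceIndex <- as.integer(referenceIndex)
  if (i < 1L || i > nT) stop("frame index out of range")
  if (referenceIndex < 1L || referenceIndex > nT)
    stop("reference index out of range")
  I0 <- X[, , referenceIndex]
  Ii <- X[, , i]
  mask <- I0 > epsCounts
  vals <- matrix(NA_real_, nrow(I0), ncol(I0))
  vals[mask] <- (I0[mask] - Ii[mask]) / I0[mask] * 100
  new("OISMap", values = vals, mask = mask, frameIndex = i,
      referenceIndex = referenceIndex)
}

#' OIS time courses over big ROIs
#'
#' Mean OIS over each 27 x 27 px ROI for every frame, with trial-phase
#' annotations.
#'
#' @param video a \linkS4class{VideoRecording} (DC-filtered,
#'   motion-compensated for the standard analysis).
#' @param rois a \linkS4class{BigROISelection}, or a k x 2 matrix of 1-based
#'   (row, col) ROI origins.
#' @param protocol a \linkS4class{TrialProtocol} for phase annotation.
#' @param roiPx ROI side when \code{rois} is a plain matrix.
#' @param referenceIndex index of I0.
#' @param epsCounts I0 mask threshold, counts.
#' @return data.frame (t, roi, ois, phase) with one row per frame and ROI;
#'   \code{phase} is "pre", "stim" or "post".
#' @export
oisTimecourse <- function(video, rois, protocol = TrialProtocol(),
                          roiPx = 27L, referenceIndex = 1L, epsCounts = 1) {
  if (is(rois, "BigROISelection")) {
    origins <- roiOrigins(rois); roiPx <- rois@roiPx
  } else origins <- rois
  X <- videoFrames(video)
  d <- dim(X)
  if (any(origins[, 1] < 1L | origins[, 2] < 1L |
          origins[, 1] + roiPx - 1L > d[1] |
          origins[, 2] + roiPx - 1L > d[2]))
    stop("ROI outside the frame")
  tF <- frameTimes(video)
  I0 <- X[, , referenceIndex]
  out <- vector("list", nrow(origins))
  for (k in seq_len(nrow(origins))) {
    rr <- origins[k, 1]:(origins[k, 1] + roiPx - 1L)
    cc <- origins[k, 2]:(origins[k, 2] + roiPx - 1L)
    i0 <- I0[rr, cc]
    keep <- i0 > epsCounts
    sub <- matrix(X[rr, cc, ], nrow = roiPx * roiPx)
    oisk <- colMeans((i0[keep] - sub[keep, , drop = FALSE]) / i0[keep]) * 100
    out[[k]] <- data.frame(t = tF, roi = k, ois = oisk)
  }
  res <- do.call(rbind, out)
  res$phase <- cut(res$t, c(-Inf, protocol@preS,
                            protocol@preS + protocol@stimS, Inf),
                   labels = c("pre", "stim", "post"))
  res
}

#' Stimulation-contact quality gate on OIS
#'
#' The increase in OIS during stimulation is the peak of the big-ROI mean
#' OIS over the stimulation phase minus its pre-stimulation mean; the trial
#' passes when the increase reaches the threshold (7% by convention —
#' below it, the electrode contact is considered ineffective and is
#' mechanically readjusted).
#'
#' @param oisSeries data.frame (t, ois) or the output of
#'   \code{\link{oisTimecourse}} (ROIs are averaged).
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param thresholdPercent gate threshold, percent.
#' @param trialId identifier carried into the result.
#' @return a list of class "qcResult": trialId, oisIncreasePercent,
#'   thresholdPercent, passed.
#' @export
qcGate <- function(oisSeries, protocol = TrialProtocol(),
                   thresholdPercent = 7, trialId = "trial") {
  agg <- stats::aggregate(ois ~ t, data = oisSeries, FUN = mean)
  pre <- agg$ois[agg$t < protocol@preS]
  stim <- agg$ois[agg$t >= protocol@preS &
                    agg$t < protocol@preS + protocol@stimS]
  if (length(pre) == 0L) stop("series does not cover the pre-stimulation phase")
  if (length(stim) == 0L) stop("series does not cover the stimulation phase")
  inc <- max(stim) - mean(pre)
  structure(list(trialId = trialId, oisIncreasePercent = inc,
                 thresholdPercent = thresholdPercent,
                 passed = inc >= thresholdPercent),
            class = "qcResult")
}

#' @export
print.qcResult <- function(x, ...) {
  cat(sprintf("QC %s: OIS increase %.2f%% (threshold %g%%) -> %s\n",
              x$trialId, x$oisIncreasePercent, x$thresholdPercent,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}
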