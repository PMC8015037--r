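# Segment-wise gradient (Lucas-Kanade-style) motion compensation.
# The frame is tiled into 16 x 16 px segments; in each segment the lateral
# offset against a fixed reference frame is estimated from the single-step
# gradient constraint, the motion-related intensity component (gradient
# times offset) is reconstructed and subtracted from the signal.

#' Build the segment tiling of a frame
#'
#' Divides a height x width frame into non-overlapping segments of nominal
#' side \code{segmentPx}; edge segments are smaller when the dimensions are
#' not multiples of the segment size. Every pixel belongs to exactly one
#' segment.
#'
#' @param heightPx,widthPx frame dimensions in pixels.
#' @param segmentPx nominal segment side (16).
#' @return a \linkS4class{SegmentGrid}.
#' @examples
#' gridDim(makeGrid(480, 752))   # 30 x 47 segments
#' @export
makeGrid <- function(heightPx, widthPx, segmentPx = 16L) {
  heightPx <- as.integer(heightPx); widthPx <- as.integer(widthPx)
  segmentPx <- as.integer(segmentPx)
  if (heightPx <= 0L || widthPx <= 0L)
    stop("frame dimensions must be positive")
  if (segmentPx <= 0L) stop("segment size must be positive")
  if (heightPx < segmentPx && widthPx < segmentPx)
    stop("frame must reach the segment size in at least one axis")
  starts <- function(n) {
    s <- seq.int(1L, n, by = segmentPx)
    list(starts = s, sizes = as.integer(pmin(s + segmentPx - 1L, n) - s + 1L))
  }
  r <- starts(heightPx); cl <- starts(widthPx)
  new("SegmentGrid", heightPx = heightPx, widthPx = widthPx,
      segmentPx = segmentPx, rowStarts = r$starts, colStarts = cl$starts,
      rowSizes = r$sizes, colSizes = cl$sizes)
}

# Central-difference spatial gradient; one-sided at the borders.
# Returns list(gx, gy): gx along columns (x), gy along rows (y).
spatialGradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w >= 3L) gx[, 2:(w - 1L)] <- (img[, 3:w] - img[, 1:(w - 2L)]) / 2
  if (w >= 2L) { gx[, 1L] <- img[, 2L] - img[, 1L]
                 gx[, w] <- img[, w] - img[, w - 1L] }
  if (h >= 3L) gy[2:(h - 1L), ] <- (img[3:h, ] - img[1:(h - 2L), ]) / 2
  if (h >= 2L) { gy[1L, ] <- img[2L, ] - img[1L, ]
                 gy[h, ] <- img[h, ] - img[h - 1L, ] }
  list(gx = gx, gy = gy)
}

# Per-pixel segment index matrix (column-major over the segment grid).
segmentIndexMap <- function(grid) {
  rowSeg <- rep.int(seq_along(grid@rowSizes), grid@rowSizes)
  colSeg <- rep.int(seq_along(grid@colSizes), grid@colSizes)
  outer(rowSeg, (colSeg - 1L) * length(grid@rowSizes), "+")
}

#' Estimate per-segment lateral offsets by the gradient method
#'
#' For each segment s and frame i the offset d = (dx, dy) minimizes the
#' gradient-constraint least squares
#' sum over segment pixels of (grad I_ref . d + (I_i - I_ref))^2,
#' where grad I_ref is the central-difference spatial gradient of the fixed
#' reference frame. With the renderer's convention (positive offset = scene
#' content moving right/down), the recovered d equals the scene
#' displacement. Segments whose 2 x 2 normal matrix is ill-conditioned
#' (condition number > 1e3 or smallest eigenvalue < 1e-6 x the segment's
#' mean squared gradient) are flagged and carry zero offset, as are
#' segments whose estimate exceeds \code{maxOffsetPx}.
#'
#' Cardiac intensity modulation can masquerade as motion (the pulsatile
#' change projects onto vessel-edge gradients); setting
#' \code{smoothFrames} to one cardiac cycle estimates the offsets on a
#' temporally moving-averaged copy of the stack, which suppresses the
#' heartbeat while preserving the (slower) tissue motion.
#'
#' @param video a \linkS4class{VideoRecording}.
#' @param grid a \linkS4class{SegmentGrid} matching the frame size.
#' @param reference index of the reference frame (first frame by default,
#'   anchoring the same frame as the OIS reference).
#' @param maxOffsetPx maximum credible offset, pixels.
#' @param conditionMax,eigenRelMin ill-conditioning thresholds.
#' @param smoothFrames odd temporal moving-average window (frames) applied
#'   before estimation; 0 disables.
#' @return a \linkS4class{MotionField}.
#' @export
estimateOffsets <- function(video, grid, reference = 1L, maxOffsetPx = 8,
                            conditionMax = 1e3, eigenRelMin = 1e-6,
                            smoothFrames = 0L) {
  X <- videoFrames(video)
  d <- dim(X)
  if (d[1] != grid@heightPx || d[2] != grid@widthPx)
    stop("grid does not match the frame size")
  if (reference < 1L || reference > d[3]) stop("reference frame out of range")
  if (smoothFrames >= 3L) {
    Xm <- matrix(X, nrow = d[1] * d[2])
    X <- array(t(centeredMAMat(t(Xm), smoothFrames)), dim = d)
  }

  ref <- X[, , reference]
  g <- spatialGradient(ref)
  segIdx <- as.vector(segmentIndexMap(grid))
  nSeg <- length(grid@rowSizes) * length(grid@colSizes)

  gxv <- as.vector(g$gx); gyv <- as.vector(g$gy)
  Sxx <- rowsum(gxv * gxv, segIdx, reorder = TRUE)[, 1]
  Sxy <- rowsum(gxv * gyv, segIdx, reorder = TRUE)[, 1]
  Syy <- rowsum(gyv * gyv, segIdx, reorder = TRUE)[, 1]
  nPix <- rowsum(rep(1, length(segIdx)), segIdx, reorder = TRUE)[, 1]

  # eigenvalues of the symmetric 2x2 normal matrices
  tr <- Sxx + Syy
  disc <- sqrt(pmax((Sxx - Syy)^2 + 4 * Sxy^2, 0))
  lamMax <- (tr + disc) / 2
  lamMin <- (tr - disc) / 2
  meanSqGrad <- (Sxx + Syy) / nPix
  illCond <- lamMin <= 0 | lamMax / pmax(lamMin, .Machine$double.eps) >
    conditionMax | lamMin < eigenRelMin * meanSqGrad
  if (all(illCond))
    warning("all segments ill-conditioned (constant reference frame?)")

  det2 <- Sxx * Syy - Sxy^2
  det2[illCond] <- 1  # avoid 0/0; flagged anyway

  nT <- d[3]
  dims <- c(length(grid@rowSizes), length(grid@colSizes), nT)
  dx <- array(0, dims); dy <- array(0, dims)
  flagged <- array(FALSE, dims)
  refv <- as.vector(ref)
  for (i in seq_len(nT)) {
    dv <- as.vector(X[, , i]) - refv
    bx <- rowsum(gxv * dv, segIdx, reorder = TRUE)[, 1]
    by <- rowsum(gyv * dv, segIdx, reorder = TRUE)[, 1]
    # solve A d = -b for each segment
    dxi <- -(Syy * bx - Sxy * by) / det2
    dyi <- -(Sxx * by - Sxy * bx) / det2
    bad <- illCond | !is.finite(dxi) | !is.finite(dyi) |
      sqrt(dxi^2 + dyi^2) > maxOffsetPx
    dxi[bad] <- 0; dyi[bad] <- 0
    dx[, , i] <- dxi; dy[, , i] <- dyi
    flagged[, , i] <- bad
  }
  new("MotionField", dx = dx, dy = dy, flagged = flagged,
      maxOffsetPx = maxOffsetPx, referenceFrame = as.integer(reference))
}

#' Subtract the reconstructed motion component from a video
#'
#' Within each segment the motion-related intensity component of frame i is
#' reconstructed as -grad I_ref . d(s, i) (the first-order intensity change
#' produced by the estimated scene offset) and subtracted, i.e.
#' corrected = I_i + grad I_ref . d. Pixels in flagged segments pass through
#' unchanged. Output values stay floating point; no re-quantization.
#'
#' @param video a \linkS4class{VideoRecording}.
#' @param field a \linkS4class{MotionField} from \code{\link{estimateOffsets}}.
#' @param grid the \linkS4class{SegmentGrid} used for estimation.
#' @return a motion-compensated \linkS4class{VideoRecording}.
#' @export
compensate <- function(video, field, grid) {
  X <- videoFrames(video)
  d <- dim(X)
  if (d[1] != grid@heightPx || d[2] != grid@widthPx)
    stop("grid does not match the frame size")
  if (!identical(dim(field@dx)[1:2],
                 c(length(grid@rowSizes), length(grid@colSizes))) ||
      dim(field@dx)[3] != d[3])
    stop("motion field does not match the video/grid shape")

  ref <- X[, , field@referenceFrame]
  g <- spatialGradient(ref)
  segMap <- segmentIndexMap(grid)
  out <- X
  for (i in seq_len(d[3])) {
    dxi <- field@dx[, , i]; dyi <- field@dy[, , i]
    if (all(dxi == 0) && all(dyi == 0)) next
    corr <- g$gx * dxi[segMap] + g$gy * dyi[segMap]
    out[, , i] <- X[, , i] + corr
  }
  VideoRecording(out, frameRate = frameRate(video),
                 pixelPitchUm = pixelPitch(video),
                 bitDepth = video@bitDepth, t0 = video@t0)
}

#' One-call motion compensation
#'
#' Convenience wrapper: builds the 16 px segment grid, estimates offsets
#' against the first frame and subtracts the reconstructed motion
#' component. When an R-peak series is supplied, offsets are estimated on
#' the heartbeat-suppressed stack (cycle-length moving average), so
#' pulsatile intensity changes do not masquerade as motion.
#'
#' @param video a \linkS4class{VideoRecording}.
#' @param segmentPx segment side, pixels.
#' @param maxOffsetPx maximum credible offset, pixels.
#' @param reference reference frame index.
#' @param rpeaks optional \linkS4class{RPeakSeries}; sets the
#'   heartbeat-suppression window for estimation.
#' @return list(video = compensated \linkS4class{VideoRecording},
#'   field = \linkS4class{MotionField}, grid = \linkS4class{SegmentGrid}).
#' @export
motionCompensate <- function(video, segmentPx = 16L, maxOffsetPx = 8,
                             reference = 1L, rpeaks = NULL) {
  d <- dim(videoFrames(video))
  grid <- makeGrid(d[1], d[2], segmentPx)
  smoothFrames <- if (is.null(rpeaks)) 0L else
    oddWindowFrames(median(diff(peakTimes(rpeaks))), frameRate(video))
  field <- estimateOffsets(video, grid, reference = reference,
                           maxOffsetPx = maxOffsetPx,
                           smoothFrames = smoothFrames)
  list(video = compensate(video, field, grid), field = field, grid = grid)
}
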