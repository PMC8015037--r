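#' Physical pixel pitch of the imaging system
#'
#' Derives micrometres per pixel from the imaged field of view and the
#' sensor resolution. The reference setup images 16.3 x 10.4 mm^2 onto
#' 752 x 480 pixels, i.e. about 21.7 um/px in both axes.
#'
#' @param fovMm field of view c(width, height) in millimetres.
#' @param resolutionPx sensor resolution c(width, height) in pixels.
#' @return micrometres per pixel (mean of the two axes).
#' @examples
#' pixelPitchUm()           # ~21.7
#' @export
pixelPitchUm <- function(fovMm = c(16.3, 10.4), resolutionPx = c(752, 480)) {
  stopifnot(length(fovMm) == 2L, length(resolutionPx) == 2L,
            all(fovMm > 0), all(resolutionPx > 0))
  mean(fovMm * 1000 / resolutionPx)
}

#' Physical side of an n x n pixel ROI
#'
#' The standard analysis windows are 3 x 3 px (about 65 um at the cranial
#' window) and 27 x 27 px (about 0.6 mm).
#'
#' @param nPx ROI side in pixels.
#' @param pitchUm micrometres per pixel (default from \code{pixelPitchUm()}).
#' @param unit "um" or "mm".
#' @return ROI side length in the requested unit.
#' @examples
#' roiPhysicalSize(3)            # ~65 um
#' roiPhysicalSize(27, unit = "mm")  # ~0.6 mm
#' @export
roiPhysicalSize <- function(nPx, pitchUm = pixelPitchUm(), unit = c("um", "mm")) {
  unit <- match.arg(unit)
  side <- nPx * pitchUm
  if (unit == "mm") side / 1000 else side
}
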