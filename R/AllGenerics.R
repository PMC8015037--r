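#' Amplitude of the pulsatile component (APC)
#'
#' Computes APC, the difference between the maximum and the minimum of a
#' cardiac-gated mean PPG pulse, expressed in percent of the DC level.
#'
#' @param object a \linkS4class{MeanPulse} (or an object from which one can
#'   be derived).
#' @param ... further arguments passed to methods.
#' @return numeric scalar, APC in percent.
#' @export
setGeneric("apc", function(object, ...) standardGeneric("apc"))

#' @rdname videoAccessors
#' @export
setGeneric("videoFrames", function(object) standardGeneric("videoFrames"))

#' @rdname videoAccessors
#' @export
setGeneric("frameRate", function(object) standardGeneric("frameRate"))

#' @rdname videoAccessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname videoAccessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))

#' @rdname videoAccessors
#' @export
setGeneric("pixelPitch", function(object) standardGeneric("pixelPitch"))

#' @rdname peakTimes
#' @export
setGeneric("peakTimes", function(object) standardGeneric("peakTimes"))

#' @rdname mapAccessors
#' @export
setGeneric("mapValues", function(object) standardGeneric("mapValues"))

#' @rdname mapAccessors
#' @export
setGeneric("mapMask", function(object) standardGeneric("mapMask"))

#' @rdname tissueAccessors
#' @export
setGeneric("vesselMask", function(object) standardGeneric("vesselMask"))

#' @rdname tissueAccessors
#' @export
setGeneric("baselineIntensity", function(object) standardGeneric("baselineIntensity"))

#' @rdname tissueAccessors
#' @export
setGeneric("electrodeXY", function(object) standardGeneric("electrodeXY"))

#' @rdname roiAccessors
#' @export
setGeneric("roiOrigins", function(object) standardGeneric("roiOrigins"))

#' @rdname roiAccessors
#' @export
setGeneric("representativeRois", function(object) standardGeneric("representativeRois"))

#' @rdname traceAccessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))

#' @rdname traceAccessors
#' @export
setGeneric("traceValues", function(object) standardGeneric("traceValues"))
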