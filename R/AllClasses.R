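#' @import methods
NULL

# ---------------------------------------------------------------------------
# Core acquisition containers
# ---------------------------------------------------------------------------

#' VideoRecording: a grayscale cranial-window frame stack
#'
#' Holds a timestamped grayscale video as a numeric array of dimension
#' height x width x frames, together with the acquisition metadata needed
#' downstream: frame rate, physical pixel pitch and sensor bit depth.
#' Pixel values live on the sensor count scale (10-bit by default, 0-1023);
#' processing stages keep them as doubles and only re-quantize on export.
#'
#' @slot frames numeric array, height x width x nFrames.
#' @slot frameRate frames per second.
#' @slot pixelPitchUm physical size of one pixel at the tissue, micrometres.
#' @slot bitDepth sensor bit depth (10 for the reference camera).
#' @slot t0 time of the first frame on the shared experiment clock, seconds.
#'
#' @name VideoRecording-class
#' @aliases VideoRecording
#' @exportClass VideoRecording
setClass("VideoRecording",
  representation(
    frames = "array",
    frameRate = "numeric",
    pixelPitchUm = "numeric",
    bitDepth = "integer",
    t0 = "numeric"
  ),
  prototype(
    frameRate = 100, pixelPitchUm = 21.676, bitDepth = 10L, t0 = 0
  ),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@frames)) != 3L)
      msg <- c(msg, "frames must be a 3-d array (height x width x time)")
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0)
      msg <- c(msg, "frameRate must be a positive scalar")
    if (object@bitDepth < 1L || object@bitDepth > 16L)
      msg <- c(msg, "bitDepth must be in 1..16")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a VideoRecording
#'
#' @param frames numeric array height x width x nFrames.
#' @param frameRate frames per second.
#' @param pixelPitchUm physical pixel pitch, micrometres per pixel.
#' @param bitDepth integer sensor bit depth.
#' @param t0 acquisition time of the first frame, seconds.
#' @return a \linkS4class{VideoRecording}.
#' @export
VideoRecording <- function(frames, frameRate = 100, pixelPitchUm = 21.676,
                           bitDepth = 10L, t0 = 0) {
  new("VideoRecording", frames = frames, frameRate = as.numeric(frameRate),
      pixelPitchUm = as.numeric(pixelPitchUm), bitDepth = as.integer(bitDepth),
      t0 = as.numeric(t0))
}

#' Video accessors
#'
#' @param object a \linkS4class{VideoRecording}.
#' @return \code{videoFrames}: the raw array; \code{frameRate}: fps;
#'   \code{nFrames}: number of frames; \code{frameTimes}: per-frame time
#'   stamps in seconds; \code{pixelPitch}: micrometres per pixel.
#' @name videoAccessors
NULL

#' @rdname videoAccessors
#' @export
setMethod("videoFrames", "VideoRecording", function(object) object@frames)

#' @rdname videoAccessors
#' @export
setMethod("frameRate", "VideoRecording", function(object) object@frameRate)

#' @rdname videoAccessors
#' @export
setMethod("nFrames", "VideoRecording", function(object) dim(object@frames)[3L])

#' @rdname videoAccessors
#' @export
setMethod("frameTimes", "VideoRecording", function(object)
  object@t0 + (seq_len(dim(object@frames)[3L]) - 1) / object@frameRate)

#' @rdname videoAccessors
#' @export
setMethod("pixelPitch", "VideoRecording", function(object) object@pixelPitchUm)

setMethod("show", "VideoRecording", function(object) {
  d <- dim(object@frames)
  cat(sprintf(
    "VideoRecording: %d x %d px, %d frames @ %.4g fps (%.1f s, %d-bit, %.3g um/px)\n",
    d[1], d[2], d[3], object@frameRate, d[3] / object@frameRate,
    object@bitDepth, object@pixelPitchUm))
})

#' ECGTrace: a single-lead electrogram synchronized to the video clock
#'
#' @slot signalMv numeric vector, millivolts.
#' @slot rateHz sampling rate, Hz.
#' @slot t0 time of the first sample on the shared clock, seconds.
#'
#' @name ECGTrace-class
#' @aliases ECGTrace
#' @exportClass ECGTrace
setClass("ECGTrace",
  representation(signalMv = "numeric", rateHz = "numeric", t0 = "numeric"),
  prototype(rateHz = 1000, t0 = 0),
  validity = function(object) {
    if (object@rateHz <= 0) "rateHz must be positive" else TRUE
  }
)

#' Construct an ECGTrace
#' @param signalMv numeric vector of samples in mV.
#' @param rateHz sampling rate in Hz (1000 for the reference setup).
#' @param t0 time of the first sample, seconds.
#' @return an \linkS4class{ECGTrace}.
#' @export
ECGTrace <- function(signalMv, rateHz = 1000, t0 = 0)
  new("ECGTrace", signalMv = as.numeric(signalMv), rateHz = as.numeric(rateHz),
      t0 = as.numeric(t0))

setMethod("show", "ECGTrace", function(object) {
  cat(sprintf("ECGTrace: %d samples @ %g Hz (%.1f s)\n",
              length(object@signalMv), object@rateHz,
              length(object@signalMv) / object@rateHz))
})

#' RPeakSeries: strictly increasing ECG R-peak times
#'
#' One cardiac cycle is the interval between two successive R-peaks; all
#' pulse gating downstream is driven by this series. Physiological guards:
#' R-R intervals must exceed 60 ms and stay below 2 s.
#'
#' @slot times numeric, strictly increasing, seconds on the video clock.
#' @slot source "detected" or "provided".
#'
#' @name RPeakSeries-class
#' @aliases RPeakSeries
#' @exportClass RPeakSeries
setClass("RPeakSeries",
  representation(times = "numeric", source = "character"),
  prototype(source = "provided"),
  validity = function(object) {
    msg <- NULL
    if (is.unsorted(object@times, strictly = TRUE))
      msg <- c(msg, "R-peak times must be strictly increasing")
    if (length(object@times) >= 2L) {
      rr <- diff(object@times)
      if (min(rr) <= 60 / 1000)
        msg <- c(msg, "minimum R-R interval must exceed 0.06 s")
      if (max(rr) >= 2)
        msg <- c(msg, "maximum R-R interval must stay below 2 s")
    }
    if (!object@source %in% c("detected", "provided"))
      msg <- c(msg, "source must be 'detected' or 'provided'")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct an RPeakSeries
#' @param times strictly increasing R-peak times, seconds.
#' @param source "detected" (from an ECG) or "provided" (external file or
#'   ground truth).
#' @return an \linkS4class{RPeakSeries}.
#' @export
RPeakSeries <- function(times, source = "provided")
  new("RPeakSeries", times = as.numeric(times), source = source)

#' R-peak times accessor
#' @param object an \linkS4class{RPeakSeries}.
#' @return numeric vector of peak times in seconds.
#' @name peakTimes
NULL

#' @rdname peakTimes
#' @export
setMethod("peakTimes", "RPeakSeries", function(object) object@times)

setMethod("show", "RPeakSeries", function(object) {
  n <- length(object@times)
  hr <- if (n >= 2) 60 / median(diff(object@times)) else NA_real_
  cat(sprintf("RPeakSeries (%s): %d peaks, median HR %.1f bpm\n",
              object@source, n, hr))
})

# ---------------------------------------------------------------------------
# Synthetic-tissue and simulation specifications
# ---------------------------------------------------------------------------

#' TissueModel: synthetic cranial-window tissue
#'
#' A per-pixel description of the simulated field of view: vessel labels
#' (0 background, 1 artery, 2 vein), mean reflectance in sensor counts on the
#' 10-bit scale, class-wise fractional pulsatilities (AC/DC amplitude of the
#' cardiac modulation) and the two stimulation-electrode positions, placed
#' adjacent to an artery as in the experimental preparation.
#'
#' @slot vesselMask integer matrix (0 = background, 1 = artery, 2 = vein).
#' @slot baselineIntensity numeric matrix, mean counts in [0, 1023].
#' @slot arteryPulsatility fractional cardiac amplitude of artery pixels.
#' @slot veinPulsatility fractional amplitude of vein pixels (< artery).
#' @slot backgroundPulsatility fractional amplitude of parenchyma pixels.
#' @slot pixelPitchUm micrometres per pixel.
#' @slot electrodeXY 2 x 2 integer matrix, rows = electrodes, cols = (row, col).
#'
#' @name TissueModel-class
#' @aliases TissueModel
#' @exportClass TissueModel
setClass("TissueModel",
  representation(
    vesselMask = "matrix",
    baselineIntensity = "matrix",
    arteryPulsatility = "numeric",
    veinPulsatility = "numeric",
    backgroundPulsatility = "numeric",
    pixelPitchUm = "numeric",
    electrodeXY = "matrix"
  ),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@vesselMask), dim(object@baselineIntensity)))
      msg <- c(msg, "vesselMask and baselineIntensity dimensions differ")
    b <- range(object@baselineIntensity)
    if (b[1] < 0 || b[2] > 1023)
      msg <- c(msg, "baselineIntensity must lie in [0, 1023]")
    if (!(object@arteryPulsatility > object@veinPulsatility &&
          object@veinPulsatility >= 0))
      msg <- c(msg, "need arteryPulsatility > veinPulsatility >= 0")
    d <- dim(object@vesselMask)
    e <- object@electrodeXY
    if (any(e[, 1] < 1 | e[, 1] > d[1] | e[, 2] < 1 | e[, 2] > d[2]))
      msg <- c(msg, "electrodes must lie inside the image")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname tissueAccessors
#' @export
setMethod("vesselMask", "TissueModel", function(object) object@vesselMask)

#' Tissue accessors
#' @param object a \linkS4class{TissueModel}.
#' @return \code{vesselMask}: integer label matrix; \code{baselineIntensity}:
#'   mean-count matrix; \code{electrodeXY}: 2 x 2 (row, col) matrix.
#' @name tissueAccessors
NULL

#' @rdname tissueAccessors
#' @export
setMethod("baselineIntensity", "TissueModel",
          function(object) object@baselineIntensity)

#' @rdname tissueAccessors
#' @export
setMethod("electrodeXY", "TissueModel", function(object) object@electrodeXY)

setMethod("show", "TissueModel", function(object) {
  d <- dim(object@vesselMask)
  cat(sprintf(
    "TissueModel: %d x %d px, %.1f%% artery / %.1f%% vein pixels\n",
    d[1], d[2], 100 * mean(object@vesselMask == 1L),
    100 * mean(object@vesselMask == 2L)))
})

#' HemoDynamicsSpec: the hemodynamic forward model
#'
#' Parameters of the simulated meningeal response to dural electrical
#' stimulation. The pulsatile amplitude is multiplied by a gain profile
#' g(t) = 1 + (stimApcGain - 1) u(t) and tissue blood volume follows
#' V(t) = 1 - stimVolumeDrop u(t), where u rises mono-exponentially during
#' the stimulation phase and relaxes mono-exponentially afterwards with
#' \code{relaxTauS} (defaults put the 2-SD return 40-90 s after onset).
#' ABP and HR show transient dips with fast recovery.
#'
#' @slot heartRateBpm nominal heart rate, beats/min (413 for the rat cohort).
#' @slot hrVariability fractional R-R jitter (SD of relative R-R deviation).
#' @slot stimApcGain multiplicative pulsatility increase at full effect, >= 1.
#' @slot stimVolumeDrop fractional reflected-intensity decrease at the
#'   stimulation peak (drives OIS), in [0, 1).
#' @slot relaxTauS mono-exponential relaxation time constant, seconds.
#' @slot apcOnsetTauS onset time constant of the pulsatility gain, seconds
#'   (faster than the volume onset: APC peaks before OIS).
#' @slot volumeOnsetTauS onset time constant of the blood-volume change, s.
#' @slot abpDipFrac fractional arterial-pressure dip during stimulation.
#' @slot hrDipFrac fractional heart-rate dip during stimulation.
#' @slot dipRecoveryTauS recovery time constant of the ABP/HR dips, s (fast).
#' @slot motionAmplitudePx peak lateral tissue offset, pixels.
#' @slot noiseSdCounts additive Gaussian sensor noise SD, counts.
#'
#' @name HemoDynamicsSpec-class
#' @aliases HemoDynamicsSpec
#' @exportClass HemoDynamicsSpec
setClass("HemoDynamicsSpec",
  representation(
    heartRateBpm = "numeric", hrVariability = "numeric",
    stimApcGain = "numeric", stimVolumeDrop = "numeric",
    relaxTauS = "numeric", apcOnsetTauS = "numeric",
    volumeOnsetTauS = "numeric",
    abpDipFrac = "numeric", hrDipFrac = "numeric",
    dipRecoveryTauS = "numeric",
    motionAmplitudePx = "numeric", noiseSdCounts = "numeric"
  ),
  prototype(
    heartRateBpm = 413, hrVariability = 0.03,
    stimApcGain = 1.5, stimVolumeDrop = 0.10,
    relaxTauS = 12, apcOnsetTauS = 3, volumeOnsetTauS = 4,
    abpDipFrac = 0.10, hrDipFrac = 0.05, dipRecoveryTauS = 4,
    motionAmplitudePx = 1.5, noiseSdCounts = 2
  ),
  validity = function(object) {
    msg <- NULL
    if (object@stimApcGain < 1) msg <- c(msg, "stimApcGain must be >= 1")
    if (object@stimVolumeDrop < 0 || object@stimVolumeDrop >= 1)
      msg <- c(msg, "stimVolumeDrop must be in [0, 1)")
    if (object@relaxTauS <= 0) msg <- c(msg, "relaxTauS must be positive")
    vals <- c(object@heartRateBpm, object@hrVariability, object@abpDipFrac,
              object@hrDipFrac, object@motionAmplitudePx,
              object@noiseSdCounts)
    if (!all(is.finite(vals))) msg <- c(msg, "all amplitudes must be finite")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a HemoDynamicsSpec
#'
#' All arguments default to the study conditions; see
#' \linkS4class{HemoDynamicsSpec} for their meaning and units.
#'
#' @param heartRateBpm,hrVariability,stimApcGain,stimVolumeDrop,relaxTauS
#'   see class slots.
#' @param apcOnsetTauS,volumeOnsetTauS,abpDipFrac,hrDipFrac,dipRecoveryTauS
#'   see class slots.
#' @param motionAmplitudePx,noiseSdCounts see class slots.
#' @return a \linkS4class{HemoDynamicsSpec}.
#' @export
HemoDynamicsSpec <- function(heartRateBpm = 413, hrVariability = 0.03,
                             stimApcGain = 1.5, stimVolumeDrop = 0.10,
                             relaxTauS = 12, apcOnsetTauS = 3,
                             volumeOnsetTauS = 4, abpDipFrac = 0.10,
                             hrDipFrac = 0.05, dipRecoveryTauS = 4,
                             motionAmplitudePx = 1.5, noiseSdCounts = 2) {
  new("HemoDynamicsSpec", heartRateBpm = heartRateBpm,
      hrVariability = hrVariability, stimApcGain = stimApcGain,
      stimVolumeDrop = stimVolumeDrop, relaxTauS = relaxTauS,
      apcOnsetTauS = apcOnsetTauS, volumeOnsetTauS = volumeOnsetTauS,
      abpDipFrac = abpDipFrac, hrDipFrac = hrDipFrac,
      dipRecoveryTauS = dipRecoveryTauS,
      motionAmplitudePx = motionAmplitudePx, noiseSdCounts = noiseSdCounts)
}

setMethod("show", "HemoDynamicsSpec", function(object) {
  cat(sprintf(
    paste0("HemoDynamicsSpec: HR %g bpm (jitter %.3g), APC gain %.3g, ",
           "volume drop %.3g, relax tau %g s\n"),
    object@heartRateBpm, object@hrVariability, object@stimApcGain,
    object@stimVolumeDrop, object@relaxTauS))
})

#' TrialProtocol: the single-trial stimulation timeline
#'
#' Default timeline is 20 s pre-stimulation, 15 s stimulation, 85 s
#' post-stimulation (120 s total), imaged at 100 fps with 1 kHz ECG.
#' The electrical stimulus (biphasic 2 ms pulses, 10 Hz, 50 V) is carried
#' as metadata only.
#'
#' @slot preS pre-stimulation phase, seconds.
#' @slot stimS stimulation phase, seconds.
#' @slot postS post-stimulation phase, seconds.
#' @slot frameRateHz video frame rate (must exceed twice the cardiac
#'   frequency).
#' @slot ecgRateHz ECG sampling rate.
#' @slot stimPulseMs,stimFreqHz,stimAmpV stimulus metadata.
#'
#' @name TrialProtocol-class
#' @aliases TrialProtocol
#' @exportClass TrialProtocol
setClass("TrialProtocol",
  representation(
    preS = "numeric", stimS = "numeric", postS = "numeric",
    frameRateHz = "numeric", ecgRateHz = "numeric",
    stimPulseMs = "numeric", stimFreqHz = "numeric", stimAmpV = "numeric"
  ),
  prototype(preS = 20, stimS = 15, postS = 85, frameRateHz = 100,
            ecgRateHz = 1000, stimPulseMs = 2, stimFreqHz = 10,
            stimAmpV = 50),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@preS, object@stimS, object@postS) < 0))
      msg <- c(msg, "phase durations must be non-negative")
    if (object@frameRateHz <= 0 || object@ecgRateHz <= 0)
      msg <- c(msg, "sampling rates must be positive")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a TrialProtocol
#'
#' @param preS,stimS,postS phase durations, seconds (20/15/85 default).
#' @param frameRateHz,ecgRateHz sampling rates, Hz.
#' @param stimPulseMs,stimFreqHz,stimAmpV stimulus metadata.
#' @return a \linkS4class{TrialProtocol}.
#' @export
TrialProtocol <- function(preS = 20, stimS = 15, postS = 85,
                          frameRateHz = 100, ecgRateHz = 1000,
                          stimPulseMs = 2, stimFreqHz = 10, stimAmpV = 50) {
  new("TrialProtocol", preS = preS, stimS = stimS, postS = postS,
      frameRateHz = frameRateHz, ecgRateHz = ecgRateHz,
      stimPulseMs = stimPulseMs, stimFreqHz = stimFreqHz,
      stimAmpV = stimAmpV)
}

#' Total trial duration
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return seconds (pre + stim + post).
#' @export
trialDuration <- function(protocol) protocol@preS + protocol@stimS + protocol@postS

setMethod("show", "TrialProtocol", function(object) {
  cat(sprintf(
    "TrialProtocol: %g/%g/%g s (pre/stim/post), video %g fps, ECG %g Hz\n",
    object@preS, object@stimS, object@postS, object@frameRateHz,
    object@ecgRateHz))
})

#' ExperimentDesign: cohort, infusion and trial schedule
#'
#' Three groups (saline control and two drug groups) each undergo three
#' baseline trials followed by three cumulative infusion steps with three
#' trials per step; trials are spaced 10 min apart and infusions 30 min
#' apart. \code{drugEffect} is a groups x steps matrix of multiplicative
#' modifiers of the stimulated pulsatility gain; \code{timeDriftPerStep}
#' is a common per-step "time-on-preparation" multiplier (> 1 reproduces
#' the progressive enhancement seen under saline, which the drugs oppose).
#'
#' @slot groupNames character vector.
#' @slot nAnimals integer vector, same length as groupNames.
#' @slot baselineTrials,infusionSteps,trialsPerStep integers (3/3/3).
#' @slot interTrialMin,interInfusionMin minutes (10/30).
#' @slot drugEffect numeric matrix groups x steps.
#' @slot timeDriftPerStep numeric scalar.
#'
#' @name ExperimentDesign-class
#' @aliases ExperimentDesign
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(
    groupNames = "character", nAnimals = "integer",
    baselineTrials = "integer", infusionSteps = "integer",
    trialsPerStep = "integer", interTrialMin = "numeric",
    interInfusionMin = "numeric", drugEffect = "matrix",
    timeDriftPerStep = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (length(object@groupNames) != length(object@nAnimals))
      msg <- c(msg, "groupNames and nAnimals lengths differ")
    if (any(object@nAnimals <= 0L))
      msg <- c(msg, "group sizes must be positive")
    if (!identical(dim(object@drugEffect),
                   c(length(object@groupNames), object@infusionSteps)))
      msg <- c(msg, "drugEffect must be groups x infusionSteps")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct an ExperimentDesign
#'
#' Defaults reproduce the study design: saline n = 11, valproate n = 10,
#' sumatriptan n = 11 (32 rats, 384 trials), 3 baseline trials, 3 infusion
#' steps x 3 trials, 10-min inter-trial and 30-min inter-infusion spacing.
#'
#' @param groupNames character vector of group labels.
#' @param nAnimals integer vector of group sizes.
#' @param baselineTrials,infusionSteps,trialsPerStep design counts.
#' @param interTrialMin,interInfusionMin schedule spacing, minutes.
#' @param drugEffect groups x steps matrix of gain multipliers (saline row
#'   is 1; drug rows < 1 model cumulative attenuation).
#' @param timeDriftPerStep common per-step drift multiplier (> 1).
#' @return an \linkS4class{ExperimentDesign}.
#' @export
ExperimentDesign <- function(groupNames = c("saline", "valproate", "sumatriptan"),
                             nAnimals = c(11L, 10L, 11L),
                             baselineTrials = 3L, infusionSteps = 3L,
                             trialsPerStep = 3L, interTrialMin = 10,
                             interInfusionMin = 30,
                             drugEffect = NULL, timeDriftPerStep = 1.25) {
  if (is.null(drugEffect)) {
    drugEffect <- rbind(
      saline = c(1, 1, 1),
      valproate = c(0.80, 0.62, 0.50),
      sumatriptan = c(0.80, 0.60, 0.45)
    )[seq_along(groupNames), , drop = FALSE]
    rownames(drugEffect) <- groupNames
    drugEffect <- drugEffect[, seq_len(infusionSteps), drop = FALSE]
  }
  new("ExperimentDesign", groupNames = groupNames,
      nAnimals = as.integer(nAnimals),
      baselineTrials = as.integer(baselineTrials),
      infusionSteps = as.integer(infusionSteps),
      trialsPerStep = as.integer(trialsPerStep),
      interTrialMin = interTrialMin, interInfusionMin = interInfusionMin,
      drugEffect = drugEffect, timeDriftPerStep = timeDriftPerStep)
}

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf(
    "ExperimentDesign: %s (total %d animals, %d trials/animal)\n",
    paste(sprintf("%s n=%d", object@groupNames, object@nAnimals),
          collapse = ", "),
    sum(object@nAnimals),
    object@baselineTrials + object@infusionSteps * object@trialsPerStep))
})

# ---------------------------------------------------------------------------
# Motion compensation
# ---------------------------------------------------------------------------

#' SegmentGrid: the 16 x 16 px tiling used for motion compensation
#'
#' Segments tile the frame exactly: edge segments may be smaller when the
#' frame dimensions are not multiples of the segment size.
#'
#' @slot heightPx,widthPx frame dimensions.
#' @slot segmentPx nominal segment side (16).
#' @slot rowStarts,colStarts 1-based top-left coordinates of segment rows
#'   and columns.
#' @slot rowSizes,colSizes actual segment extents.
#'
#' @name SegmentGrid-class
#' @aliases SegmentGrid
#' @exportClass SegmentGrid
setClass("SegmentGrid",
  representation(
    heightPx = "integer", widthPx = "integer", segmentPx = "integer",
    rowStarts = "integer", colStarts = "integer",
    rowSizes = "integer", colSizes = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (sum(object@rowSizes) != object@heightPx ||
        sum(object@colSizes) != object@widthPx)
      msg <- c(msg, "segments must tile the frame exactly")
    if (is.null(msg)) TRUE else msg
  }
)

#' Number of segments in a SegmentGrid
#' @param grid a \linkS4class{SegmentGrid}.
#' @return integer vector c(nRows, nCols).
#' @export
gridDim <- function(grid) c(length(grid@rowStarts), length(grid@colStarts))

setMethod("show", "SegmentGrid", function(object) {
  cat(sprintf("SegmentGrid: %d x %d segments (nominal %d px) over %d x %d px\n",
              length(object@rowStarts), length(object@colStarts),
              object@segmentPx, object@heightPx, object@widthPx))
})

#' MotionField: per-frame, per-segment lateral offsets
#'
#' Offsets are sub-pixel estimates of the scene displacement of each segment
#' relative to the reference frame; ill-conditioned segments (no texture)
#' are flagged and carry zero offset, as do segments whose estimate exceeds
#' \code{maxOffsetPx}.
#'
#' @slot dx,dy numeric arrays segRows x segCols x nFrames (pixels; dx is
#'   the column/x direction, dy the row/y direction).
#' @slot flagged logical array of the same shape.
#' @slot maxOffsetPx offset bound, pixels.
#' @slot referenceFrame index of the reference frame.
#'
#' @name MotionField-class
#' @aliases MotionField
#' @exportClass MotionField
setClass("MotionField",
  representation(dx = "array", dy = "array", flagged = "array",
                 maxOffsetPx = "numeric", referenceFrame = "integer"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@dx), dim(object@dy)) ||
        !identical(dim(object@dx), dim(object@flagged)))
      msg <- c(msg, "dx, dy and flagged must share dimensions")
    ok <- object@flagged | (sqrt(object@dx^2 + object@dy^2) <=
                              object@maxOffsetPx + 1e-9)
    if (!all(ok))
      msg <- c(msg, "unflagged offsets must respect maxOffsetPx")
    if (any(object@flagged & (object@dx != 0 | object@dy != 0)))
      msg <- c(msg, "flagged segments must carry zero offset")
    if (is.null(msg)) TRUE else msg
  }
)

setMethod("show", "MotionField", function(object) {
  cat(sprintf(
    "MotionField: %d x %d segments x %d frames, %.2f%% flagged, max |d| %.2f px\n",
    dim(object@dx)[1], dim(object@dx)[2], dim(object@dx)[3],
    100 * mean(object@flagged),
    max(sqrt(object@dx^2 + object@dy^2))))
})

# ---------------------------------------------------------------------------
# PPG waveforms, pulses and maps
# ---------------------------------------------------------------------------

#' PPGWaveform: the AC/DC waveform of one 3 x 3 px ROI
#'
#' \code{raw} is the frame-by-frame mean of the 9 ROI pixels; \code{dc} its
#' centered moving average over one median cardiac cycle; \code{acOverDc}
#' the normalized pulsatile waveform (raw - dc)/dc.
#'
#' @slot roiOrigin integer (row, col) of the ROI top-left pixel, 1-based.
#' @slot t frame time stamps, seconds.
#' @slot raw,dc,acOverDc numeric series.
#' @slot valid FALSE when dc was non-positive anywhere.
#'
#' @name PPGWaveform-class
#' @aliases PPGWaveform
#' @exportClass PPGWaveform
setClass("PPGWaveform",
  representation(roiOrigin = "integer", t = "numeric", raw = "numeric",
                 dc = "numeric", acOverDc = "numeric", valid = "logical"),
  validity = function(object) {
    n <- length(object@t)
    if (length(object@raw) != n || length(object@dc) != n ||
        length(object@acOverDc) != n)
      "t, raw, dc and acOverDc must have equal length" else TRUE
  }
)

#' @rdname traceAccessors
#' @export
setMethod("traceTimes", "PPGWaveform", function(object) object@t)

#' @rdname traceAccessors
#' @export
setMethod("traceValues", "PPGWaveform", function(object) object@acOverDc)

setMethod("show", "PPGWaveform", function(object) {
  cat(sprintf("PPGWaveform: ROI @ (%d,%d), %d samples, valid = %s\n",
              object@roiOrigin[1], object@roiOrigin[2], length(object@t),
              object@valid))
})

#' MeanPulse: the 10-cycle ensemble-averaged cardiac pulse
#'
#' Each R-R interval of the AC/DC waveform is resampled to a fixed number of
#' phase points by linear interpolation and averaged point-wise over the
#' cycles in the window.
#'
#' @slot phase normalized cardiac phase in [0, 1).
#' @slot values mean AC/DC value at each phase point.
#' @slot nCycles number of cycles averaged (10 by convention).
#' @slot windowCenterS temporal center of the averaging window, seconds.
#'
#' @name MeanPulse-class
#' @aliases MeanPulse
#' @exportClass MeanPulse
setClass("MeanPulse",
  representation(phase = "numeric", values = "numeric", nCycles = "integer",
                 windowCenterS = "numeric"),
  validity = function(object) {
    if (length(object@phase) != length(object@values))
      "phase and values must have equal length" else TRUE
  }
)

setMethod("show", "MeanPulse", function(object) {
  cat(sprintf(
    "MeanPulse: %d phase points, %d cycles centred at %.2f s, APC = %.3f%%\n",
    length(object@phase), object@nCycles, object@windowCenterS,
    100 * (max(object@values) - min(object@values))))
})

#' APCMap: per-tile pulsatile-amplitude map
#'
#' APC in percent on the grid of non-overlapping 3 x 3 px ROIs anchored at
#' the image origin; residual rows/columns that do not fill a tile are
#' masked out.
#'
#' @slot values numeric matrix floor(H/3) x floor(W/3), percent.
#' @slot mask logical matrix, TRUE where the tile is valid.
#' @slot roiPx tile side in pixels (3).
#' @slot timestampS center time of the 10-cycle window used.
#'
#' @name APCMap-class
#' @aliases APCMap
#' @exportClass APCMap
setClass("APCMap",
  representation(values = "matrix", mask = "matrix", roiPx = "integer",
                 timestampS = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), dim(object@mask)))
      msg <- c(msg, "values and mask dimensions differ")
    if (any(object@values[object@mask] < 0, na.rm = TRUE))
      msg <- c(msg, "APC must be non-negative on valid tiles")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname mapAccessors
#' @export
setMethod("mapValues", "APCMap", function(object) object@values)

#' Map accessors
#' @param object an \linkS4class{APCMap} or \linkS4class{OISMap}.
#' @return \code{mapValues}: numeric matrix in percent; \code{mapMask}:
#'   logical validity matrix.
#' @name mapAccessors
NULL

#' @rdname mapAccessors
#' @export
setMethod("mapMask", "APCMap", function(object) object@mask)

setMethod("show", "APCMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf(
    "APCMap: %d x %d tiles (%d px) @ %.2f s, median APC %.3f%%\n",
    dim(object@values)[1], dim(object@values)[2], object@roiPx,
    object@timestampS, median(v, na.rm = TRUE)))
})

#' OISMap: per-pixel optical intrinsic signal
#'
#' OIS_i(x, y) = (I0 - I_i)/I0 * 100 with I0 the first pre-stimulation
#' frame; positive values indicate increased blood volume (darker tissue
#' under green light). Pixels with I0 at or below the mask threshold are
#' invalid.
#'
#' @slot values numeric matrix, percent.
#' @slot mask logical matrix.
#' @slot frameIndex index i of the mapped frame.
#' @slot referenceIndex index of I0.
#'
#' @name OISMap-class
#' @aliases OISMap
#' @exportClass OISMap
setClass("OISMap",
  representation(values = "matrix", mask = "matrix", frameIndex = "integer",
                 referenceIndex = "integer"),
  validity = function(object) {
    if (!identical(dim(object@values), dim(object@mask)))
      "values and mask dimensions differ" else TRUE
  }
)

#' @rdname mapAccessors
#' @export
setMethod("mapValues", "OISMap", function(object) object@values)

#' @rdname mapAccessors
#' @export
setMethod("mapMask", "OISMap", function(object) object@mask)

setMethod("show", "OISMap", function(object) {
  cat(sprintf("OISMap: frame %d vs reference %d, mean OIS %.2f%%\n",
              object@frameIndex, object@referenceIndex,
              mean(object@values[object@mask])))
})

# ---------------------------------------------------------------------------
# Response containers
# ---------------------------------------------------------------------------

#' BigROISelection: the six 27 x 27 px analysis windows
#'
#' Selected on the APC map computed at the 10th second of stimulation, at
#' the locations of highest pulsatile amplitude; the two windows nearest
#' the stimulation electrodes are flagged representative and drive the
#' per-trial APC/OIS traces.
#'
#' @slot origins k x 2 integer matrix of 1-based (row, col) top-left pixels.
#' @slot representative logical vector (exactly two TRUE).
#' @slot roiPx window side, pixels (27).
#' @slot meanApc mean APC of each window at selection time, percent.
#'
#' @name BigROISelection-class
#' @aliases BigROISelection
#' @exportClass BigROISelection
setClass("BigROISelection",
  representation(origins = "matrix", representative = "logical",
                 roiPx = "integer", meanApc = "numeric"),
  validity = function(object) {
    msg <- NULL
    k <- nrow(object@origins)
    if (length(object@representative) != k)
      msg <- c(msg, "representative flag per ROI required")
    if (sum(object@representative) != 2L)
      msg <- c(msg, "exactly two representative ROIs required")
    # pairwise non-overlap
    if (k >= 2L) {
      o <- object@origins; s <- object@roiPx
      for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
        if (abs(o[i, 1] - o[j, 1]) < s && abs(o[i, 2] - o[j, 2]) < s)
          msg <- c(msg, "ROIs must not overlap")
      }
    }
    if (is.null(msg)) TRUE else unique(msg)
  }
)

#' @rdname roiAccessors
#' @export
setMethod("roiOrigins", "BigROISelection", function(object) object@origins)

#' Big-ROI accessors
#' @param object a \linkS4class{BigROISelection}.
#' @return \code{roiOrigins}: k x 2 (row, col) matrix;
#'   \code{representativeRois}: logical vector marking the two
#'   electrode-adjacent windows.
#' @name roiAccessors
NULL

#' @rdname roiAccessors
#' @export
setMethod("representativeRois", "BigROISelection",
          function(object) object@representative)

setMethod("show", "BigROISelection", function(object) {
  cat(sprintf("BigROISelection: %d ROIs of %d px, representative: %s\n",
              nrow(object@origins), object@roiPx,
              paste(which(object@representative), collapse = ", ")))
})

#' NormalizedTrace: a parameter trace normalized to its pre-stimulation mean
#'
#' Values are percentages of the mean over the pre-stimulation phase (the
#' first \code{preS} seconds), which therefore averages exactly 100.
#'
#' @slot parameter one of "APC", "OIS", "ABP", "HR".
#' @slot t time stamps, seconds from trial start.
#' @slot values percent of pre-stimulation mean.
#' @slot preStimSD SD of the normalized pre-stimulation samples, percent.
#' @slot preS duration of the pre-stimulation phase, seconds.
#'
#' @name NormalizedTrace-class
#' @aliases NormalizedTrace
#' @exportClass NormalizedTrace
setClass("NormalizedTrace",
  representation(parameter = "character", t = "numeric", values = "numeric",
                 preStimSD = "numeric", preS = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@t) != length(object@values))
      msg <- c(msg, "t and values must have equal length")
    pre <- object@values[object@t < object@preS]
    if (length(pre) >= 2L && abs(mean(pre) - 100) > 1e-6)
      msg <- c(msg, "pre-stimulation mean must equal 100%")
    if (is.null(msg)) TRUE else msg
  }
)

#' @rdname traceAccessors
#' @export
setMethod("traceTimes", "NormalizedTrace", function(object) object@t)

#' Trace accessors
#' @param object a \linkS4class{NormalizedTrace} or \linkS4class{PPGWaveform}.
#' @return \code{traceTimes}: seconds; \code{traceValues}: the normalized
#'   (percent) or AC/DC (dimensionless) series.
#' @name traceAccessors
NULL

#' @rdname traceAccessors
#' @export
setMethod("traceValues", "NormalizedTrace", function(object) object@values)

setMethod("show", "NormalizedTrace", function(object) {
  cat(sprintf(
    "NormalizedTrace (%s): %d samples over %.1f s, pre-stim SD %.2f%%\n",
    object@parameter, length(object@t), diff(range(object@t)),
    object@preStimSD))
})

#' ExperimentDataset: a simulated multi-animal experiment
#'
#' One record per trial per animal with the scheduled start time, the
#' ground-truth stimulated gain applied, and (trace-level simulation)
#' per-trial raw parameter traces ready for normalization and integral
#' metrics.
#'
#' @slot schedule data.frame with one row per trial (animal, group, stage,
#'   trial, tStartMin, gainMult and friends).
#' @slot traces list parallel to schedule rows; each element a data.frame
#'   with columns t, apc, ois, abp, hr (raw, unnormalized units).
#' @slot groundTruth data.frame of injected per-stage gain multipliers.
#' @slot design the \linkS4class{ExperimentDesign} used.
#' @slot protocol the \linkS4class{TrialProtocol} used.
#' @slot hemo the base \linkS4class{HemoDynamicsSpec}.
#'
#' @name ExperimentDataset-class
#' @aliases ExperimentDataset
#' @exportClass ExperimentDataset
setClass("ExperimentDataset",
  representation(schedule = "data.frame", traces = "list",
                 groundTruth = "data.frame", design = "ExperimentDesign",
                 protocol = "TrialProtocol", hemo = "HemoDynamicsSpec"),
  validity = function(object) {
    if (length(object@traces) > 0L &&
        length(object@traces) != nrow(object@schedule))
      "traces must parallel schedule rows" else TRUE
  }
)

setMethod("show", "ExperimentDataset", function(object) {
  cat(sprintf("ExperimentDataset: %d trials, %d animals, %d groups\n",
              nrow(object@schedule), length(unique(object@schedule$animal)),
              length(unique(object@schedule$group))))
})

#' Schedule accessor
#' @param dataset an \linkS4class{ExperimentDataset}.
#' @return the per-trial schedule data.frame.
#' @export
trialSchedule <- function(dataset) dataset@schedule

#' Ground-truth effect table accessor
#' @param dataset an \linkS4class{ExperimentDataset}.
#' @return data.frame of injected per-stage gain multipliers.
#' @export
groundTruthEffects <- function(dataset) dataset@groundTruth
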