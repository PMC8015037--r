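#' TrialSimulation: one synthetic stimulation trial with ground truth
#'
#' @slot video the rendered \linkS4class{VideoRecording}.
#' @slot ecg the synchronized \linkS4class{ECGTrace}.
#' @slot rpeaks ground-truth \linkS4class{RPeakSeries}.
#' @slot abp data.frame (t, mmHg): arterial blood pressure trace.
#' @slot hr data.frame (t, bpm): instantaneous heart-rate trace.
#' @slot groundTruth list of injected profiles (see
#'   \code{\link{simulateTrial}}).
#' @slot clippedCount number of pixel values clipped at the bit-depth limit.
#'
#' @name TrialSimulation-class
#' @aliases TrialSimulation
#' @exportClass TrialSimulation
setClass("TrialSimulation",
  representation(video = "VideoRecording", ecg = "ECGTrace",
                 rpeaks = "RPeakSeries", abp = "data.frame",
                 hr = "data.frame", groundTruth = "list",
                 clippedCount = "integer"))

setMethod("show", "TrialSimulation", function(object) {
  cat("TrialSimulation:\n  ")
  show(object@video)
  cat(sprintf("  %d R-peaks, %d clipped pixel values\n",
              length(peakTimes(object@rpeaks)), object@clippedCount))
})

#' Simulate one cranial-window stimulation trial
#'
#' Renders a synthetic video with the forward model
#' I(p, t) = clip( B(p) V(t) [1 + a(p) g(t) c(phi(t))] ),
#' where B is the tissue baseline intensity, V the slow blood-volume
#' intensity factor, a the per-pixel fractional pulsatility, g the
#' stimulation gain profile and c the zero-mean cardiac template evaluated
#' at the cardiac phase phi derived from the generated R-peaks. Lateral
#' tissue motion is applied by sub-pixel bilinear warping of the ideal
#' frame, then Gaussian sensor noise is added and values are clipped to the
#' 10-bit range (clipping is counted and reported). A synchronized ECG
#' (1 ms-accurate shared clock), ABP and HR traces are generated alongside.
#'
#' @param tissue a \linkS4class{TissueModel}.
#' @param hemo a \linkS4class{HemoDynamicsSpec}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param seed integer RNG seed; identical inputs give bit-identical output.
#' @param baseAbpMmHg mean arterial pressure before stimulation (72 mmHg in
#'   the reference cohort).
#' @param traceRateHz sampling rate of the ABP/HR traces.
#' @return a \linkS4class{TrialSimulation}. Its \code{groundTruth} list
#'   carries \code{t} (frame times), \code{gain} g(t), \code{volume} V(t),
#'   \code{apcPercent} (injected APC in percent per pixel class over time),
#'   \code{pulsatility} (class amplitudes), \code{motion} (dx, dy per frame)
#'   and \code{rpeaks}.
#' @examples
#' tis <- makeTissue(1, 64, 64)
#' pr <- TrialProtocol(preS = 2, stimS = 2, postS = 2, frameRateHz = 40)
#' sim <- simulateTrial(tis, HemoDynamicsSpec(motionAmplitudePx = 0), pr, seed = 1)
#' sim
#' @export
simulateTrial <- function(tissue, hemo, protocol, seed,
                          baseAbpMmHg = 72, traceRateHz = 10) {
  set.seed(as.integer(seed))
  durS <- trialDuration(protocol)
  fps <- protocol@frameRateHz
  if (fps <= 2 * hemo@heartRateBpm / 60)
    stop("frame rate must exceed twice the cardiac frequency")
  nF <- as.integer(round(durS * fps))
  # frame timestamps quantized to the 1 kHz ECG clock (1 ms sync accuracy)
  tFrames <- round(((seq_len(nF) - 1) / fps) * 1000) / 1000

  rpeaks <- generateRPeaks(durS, hemo, protocol)
  rt <- peakTimes(rpeaks)

  # cardiac phase per frame: linear within each R-R interval, periodic
  # extrapolation before the first / after the last peak
  rrMed <- median(diff(rt))
  knots <- c(rt[1] - rrMed, rt, rt[length(rt)] + rrMed)
  cyc <- stats::approx(knots, seq_along(knots) - 1, xout = tFrames,
                       rule = 2)$y
  cVals <- cardiacTemplate(cyc %% 1)

  gVals <- apcGainProfile(tFrames, hemo, protocol)
  vVals <- volumeFactorProfile(tFrames, hemo, protocol)

  # motion path: low-pass-filtered random walk scaled to the peak amplitude
  if (hemo@motionAmplitudePx > 0) {
    mkPath <- function() {
      p <- gaussianSmooth(cumsum(stats::rnorm(nF)), sigma = fps * 0.15)
      p <- p - mean(p)
      p
    }
    mdx <- mkPath(); mdy <- mkPath()
    sc <- hemo@motionAmplitudePx / max(sqrt(mdx^2 + mdy^2), 1e-12)
    mdx <- mdx * sc; mdy <- mdy * sc
  } else {
    mdx <- numeric(nF); mdy <- numeric(nF)
  }

  B <- tissue@baselineIntensity
  a <- pulsatilityMap(tissue)
  Ba <- B * a
  h <- nrow(B); w <- ncol(B)
  frames <- array(0, dim = c(h, w, nF))
  nClipped <- 0L
  for (i in seq_len(nF)) {
    f <- vVals[i] * (B + Ba * (gVals[i] * cVals[i]))
    if (mdx[i] != 0 || mdy[i] != 0) f <- bilinearShift(f, mdx[i], mdy[i])
    if (hemo@noiseSdCounts > 0)
      f <- f + stats::rnorm(h * w, 0, hemo@noiseSdCounts)
    cl <- clipCounts(f)
    nClipped <- nClipped + cl$nClipped
    frames[, , i] <- cl$values
  }
  if (nClipped > 0L)
    warning(sprintf("%d pixel values clipped at the 10-bit range", nClipped))

  video <- VideoRecording(frames, frameRate = fps,
                          pixelPitchUm = tissue@pixelPitchUm)
  ecg <- synthesizeECG(rpeaks, durS, rateHz = protocol@ecgRateHz)

  tTrace <- seq(0, durS - 1 / traceRateHz, by = 1 / traceRateHz)
  abp <- data.frame(
    t = tTrace,
    mmHg = baseAbpMmHg * (1 - hemo@abpDipFrac *
                            dipProfile(tTrace, hemo, protocol)) +
      stats::rnorm(length(tTrace), 0, 1.0))
  rrMid <- (rt[-1] + rt[-length(rt)]) / 2
  hrInst <- 60 / diff(rt)
  hr <- data.frame(
    t = tTrace,
    bpm = stats::approx(rrMid, hrInst, xout = tTrace, rule = 2)$y)

  gt <- list(
    t = tFrames, gain = gVals, volume = vVals,
    pulsatility = c(artery = tissue@arteryPulsatility,
                    vein = tissue@veinPulsatility,
                    background = tissue@backgroundPulsatility),
    apcPercent = list(artery = 100 * tissue@arteryPulsatility * gVals,
                      vein = 100 * tissue@veinPulsatility * gVals,
                      background = 100 * tissue@backgroundPulsatility * gVals),
    motion = data.frame(t = tFrames, dx = mdx, dy = mdy),
    rpeaks = rt)

  new("TrialSimulation", video = video, ecg = ecg, rpeaks = rpeaks,
      abp = abp, hr = hr, groundTruth = gt, clippedCount = nClipped)
}
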