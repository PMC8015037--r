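# Shared hemodynamic kinetics: every synthetic signal (video, parameter
# traces, ABP/HR) is driven by the same small set of profile functions, so
# analytic ground truth is available for all of them.

#' Cardiac pulse template
#'
#' A fixed asymmetric arterial pulse shape over one normalized cardiac
#' cycle: raised-cosine fast rise (fraction \code{riseFrac} of the cycle)
#' followed by a raised-cosine slow decay. The template is zero-mean, so the
#' temporal mean of a pulsatile pixel equals its baseline exactly, and has
#' max - min = 1, so the injected fractional pulse amplitude at a pixel is
#' directly pulsatility x gain.
#'
#' @param phase numeric vector of cardiac phases in [0, 1).
#' @param riseFrac fraction of the cycle occupied by the systolic rise.
#' @return numeric vector, zero-mean, max - min = 1.
#' @export
cardiacTemplate <- function(phase, riseFrac = 0.4) {
  phase <- phase %% 1
  up <- phase < riseFrac
  c0 <- numeric(length(phase))
  c0[up] <- 0.5 - 0.5 * cos(pi * phase[up] / riseFrac)
  c0[!up] <- 0.5 + 0.5 * cos(pi * (phase[!up] - riseFrac) / (1 - riseFrac))
  c0 - 0.5  # each half-cosine has mean 0.5, so this is exactly zero-mean
}

#' Stimulation-response kinetic profile
#'
#' Normalized response u(t) in [0, 1]: zero before stimulation onset,
#' mono-exponential rise with \code{onsetTauS} during the stimulation phase,
#' mono-exponential relaxation with \code{relaxTauS} afterwards.
#'
#' @param t times, seconds from trial start.
#' @param protocol a \linkS4class{TrialProtocol} (supplies the 20/15/85 s
#'   phase boundaries).
#' @param onsetTauS onset time constant, seconds.
#' @param relaxTauS relaxation time constant, seconds.
#' @return numeric vector of u(t) values.
#' @export
stimResponseProfile <- function(t, protocol, onsetTauS, relaxTauS) {
  t1 <- protocol@preS
  t2 <- protocol@preS + protocol@stimS
  u <- numeric(length(t))
  during <- t >= t1 & t < t2
  after <- t >= t2
  u[during] <- 1 - exp(-(t[during] - t1) / onsetTauS)
  uEnd <- 1 - exp(-(t2 - t1) / onsetTauS)
  u[after] <- uEnd * exp(-(t[after] - t2) / relaxTauS)
  u
}

#' Pulsatility gain profile g(t)
#'
#' g(t) = 1 + (stimApcGain - 1) u(t) with the APC onset/relaxation time
#' constants; multiplies the tissue's fractional pulsatility.
#'
#' @param t times, seconds.
#' @param hemo a \linkS4class{HemoDynamicsSpec}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return numeric vector of gains (>= 1).
#' @export
apcGainProfile <- function(t, hemo, protocol) {
  1 + (hemo@stimApcGain - 1) *
    stimResponseProfile(t, protocol, hemo@apcOnsetTauS, hemo@relaxTauS)
}

#' Blood-volume intensity factor V(t)
#'
#' V(t) = 1 - stimVolumeDrop u(t): the slowly varying multiplicative factor
#' on reflected intensity. Increased blood volume absorbs more green light,
#' so intensity drops and OIS (defined as a relative intensity decrease)
#' rises by 100 x stimVolumeDrop x u(t) percent.
#'
#' @inheritParams apcGainProfile
#' @return numeric vector of intensity factors in (0, 1].
#' @export
volumeFactorProfile <- function(t, hemo, protocol) {
  1 - hemo@stimVolumeDrop *
    stimResponseProfile(t, protocol, hemo@volumeOnsetTauS, hemo@relaxTauS)
}

# Fast-recovering dip profile shared by ABP and HR (systemic reaction is
# much faster than the optical parameters).
dipProfile <- function(t, hemo, protocol) {
  stimResponseProfile(t, protocol, onsetTauS = 2,
                      relaxTauS = hemo@dipRecoveryTauS)
}

#' Closed-form stimulation-window integral of the normalized APC trace
#'
#' On a noise-free trial the normalized APC trace is
#' 100 g(t), so its integral above the 100% pre-stimulation level over the
#' stimulation phase [preS, preS + stimS] is
#' 100 (stimApcGain - 1) [stimS - tau (1 - exp(-stimS/tau))] percent-seconds
#' with tau the APC onset time constant. Used as an independent oracle for
#' the trapezoidal integral metric.
#'
#' @param hemo a \linkS4class{HemoDynamicsSpec}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return integral in percent-seconds.
#' @export
integralStimAnalytic <- function(hemo, protocol) {
  Tst <- protocol@stimS
  tau <- hemo@apcOnsetTauS
  100 * (hemo@stimApcGain - 1) * (Tst - tau * (1 - exp(-Tst / tau)))
}

#' Generate ground-truth R-peak times
#'
#' Cardiac cycles are generated sequentially from the instantaneous heart
#' rate (nominal rate modulated by the stimulation-evoked dip) with
#' fractional R-R jitter \code{hrVariability}. Uses the current RNG state;
#' seed at the call site for determinism.
#'
#' @param durationS trial duration, seconds.
#' @param hemo a \linkS4class{HemoDynamicsSpec}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return an \linkS4class{RPeakSeries} with source "provided".
#' @export
generateRPeaks <- function(durationS, hemo, protocol) {
  tms <- numeric(0)
  tcur <- 0.2 * 60 / hemo@heartRateBpm   # first beat shortly after start
  while (tcur < durationS) {
    tms <- c(tms, tcur)
    hrNow <- hemo@heartRateBpm *
      (1 - hemo@hrDipFrac * dipProfile(tcur, hemo, protocol))
    jit <- if (hemo@hrVariability > 0)
      max(-0.5, stats::rnorm(1L, 0, hemo@hrVariability)) else 0
    tcur <- tcur + (60 / hrNow) * (1 + jit)
  }
  RPeakSeries(tms, source = "provided")
}

#' Synthesize an ECG trace with visible R-peaks
#'
#' Gaussian QRS-like deflections (1 mV, 4 ms width) at the given R-peak
#' times on a noisy baseline; morphology beyond a detectable R-peak is not
#' modeled. Uses the current RNG state for the baseline noise.
#'
#' @param rpeaks an \linkS4class{RPeakSeries}.
#' @param durationS trace duration, seconds.
#' @param rateHz sampling rate, Hz (1000 in the reference setup).
#' @param noiseSdMv baseline noise SD, millivolts.
#' @return an \linkS4class{ECGTrace}.
#' @export
synthesizeECG <- function(rpeaks, durationS, rateHz = 1000, noiseSdMv = 0.02) {
  n <- as.integer(round(durationS * rateHz))
  t <- (seq_len(n) - 1) / rateHz
  sig <- stats::rnorm(n, 0, noiseSdMv)
  sigma <- 0.004
  for (tp in peakTimes(rpeaks)) {
    idx <- which(t >= tp - 5 * sigma & t <= tp + 5 * sigma)
    sig[idx] <- sig[idx] + exp(-0.5 * ((t[idx] - tp) / sigma)^2)
  }
  ECGTrace(sig, rateHz = rateHz)
}
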