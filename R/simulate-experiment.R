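# Trace-level forward model of a full multi-animal infusion experiment.
# Per-trial parameter traces are generated analytically from the same
# kinetics used for video rendering, so cohort-scale simulations (hundreds
# of 120 s trials) remain tractable while sharing ground truth with the
# pixel-level generator; per-trial videos are available via simulateTrial().

#' Simulate raw parameter traces for a single trial
#'
#' Generates the four per-trial parameter traces (APC, OIS, ABP, HR) in raw
#' units directly from the hemodynamic kinetics, without rendering video.
#' \code{gainMult} scales the stimulation-evoked pulsatility excess:
#' the effective gain profile is 1 + (stimApcGain - 1) gainMult u(t).
#' The OIS parameter trace is reported as 100 + OIS (percent), i.e. the
#' inverted normalized DC intensity, whose pre-stimulation mean is ~100 and
#' whose excess above 100 equals OIS.
#'
#' @param hemo a \linkS4class{HemoDynamicsSpec}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param gainMult multiplier on the stimulation-evoked pulsatility excess
#'   (1 = the base response; drugs < 1; time drift > 1).
#' @param rateHz trace sampling rate.
#' @param baseApcPercent pre-stimulation APC level, percent (2% for the
#'   default artery pulsatility).
#' @param baseAbpMmHg,baseHrBpm pre-stimulation systemic levels.
#' @param noise named list of noise SDs: \code{apcRel} (relative, on APC),
#'   \code{oisAbs} (percent), \code{abpAbs} (mmHg), \code{hrAbs} (bpm).
#' @return data.frame with columns t, apc, ois, abp, hr.
#' @export
simulateTrialTraces <- function(hemo, protocol, gainMult = 1, rateHz = 10,
                                baseApcPercent = 2, baseAbpMmHg = 72,
                                baseHrBpm = NULL,
                                noise = list(apcRel = 0.02, oisAbs = 0.5,
                                             abpAbs = 1.0, hrAbs = 3.0)) {
  if (is.null(baseHrBpm)) baseHrBpm <- hemo@heartRateBpm
  durS <- trialDuration(protocol)
  t <- seq(0, durS - 1 / rateHz, by = 1 / rateHz)
  n <- length(t)
  uA <- stimResponseProfile(t, protocol, hemo@apcOnsetTauS, hemo@relaxTauS)
  gEff <- 1 + (hemo@stimApcGain - 1) * gainMult * uA
  uV <- stimResponseProfile(t, protocol, hemo@volumeOnsetTauS, hemo@relaxTauS)
  dip <- dipProfile(t, hemo, protocol)
  data.frame(
    t = t,
    apc = baseApcPercent * gEff * (1 + stats::rnorm(n, 0, noise$apcRel)),
    ois = 100 + 100 * hemo@stimVolumeDrop * uV +
      stats::rnorm(n, 0, noise$oisAbs),
    abp = baseAbpMmHg * (1 - hemo@abpDipFrac * dip) +
      stats::rnorm(n, 0, noise$abpAbs),
    hr = baseHrBpm * (1 - hemo@hrDipFrac * dip) +
      stats::rnorm(n, 0, noise$hrAbs))
}

#' Simulate a full multi-animal infusion experiment
#'
#' Builds the trial schedule of the study design (three baseline trials
#' 10 min apart, then three infusion steps 30 min apart with three trials
#' each), applies the group- and step-specific effect multipliers to the
#' stimulation-evoked pulsatility excess from the matching infusion step
#' onward, and simulates per-trial parameter traces with animal- and
#' trial-level lognormal variability. The injected effect table is returned
#' as ground truth.
#'
#' The per-stage multiplier is \code{timeDriftPerStep^step *
#' drugEffect[group, step]}: with the default drift > 1 and saline
#' multipliers of 1 the saline response grows across steps, while the drug
#' rows oppose the drift (cumulative attenuation).
#'
#' @param design an \linkS4class{ExperimentDesign}.
#' @param hemo base \linkS4class{HemoDynamicsSpec}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param seed integer RNG seed.
#' @param traceRateHz per-trial trace sampling rate.
#' @param animalSdLog SD of the per-animal lognormal response factor.
#' @param trialSdLog SD of the per-trial lognormal response factor.
#' @param renderVideo if TRUE, also renders one video per trial via
#'   \code{\link{simulateTrial}} (heavy; intended for single-trial or tiny
#'   designs) and stores the \linkS4class{TrialSimulation}s alongside.
#' @return an \linkS4class{ExperimentDataset}.
#' @examples
#' ds <- simulateExperiment(ExperimentDesign(), seed = 1)
#' nrow(trialSchedule(ds))   # 384 trials for the default design
#' @export
simulateExperiment <- function(design, hemo = HemoDynamicsSpec(),
                               protocol = TrialProtocol(), seed = 1,
                               traceRateHz = 10, animalSdLog = 0.10,
                               trialSdLog = 0.05, renderVideo = FALSE) {
  set.seed(as.integer(seed))
  stages <- c("baseline", paste0("step", seq_len(design@infusionSteps)))
  stageMult <- function(g, stage) {
    if (stage == "baseline") return(1)
    k <- as.integer(sub("step", "", stage))
    design@timeDriftPerStep^k * design@drugEffect[g, k]
  }

  rows <- list(); traces <- list(); videos <- list()
  animalId <- 0L
  for (g in seq_along(design@groupNames)) {
    for (i in seq_len(design@nAnimals[g])) {
      animalId <- animalId + 1L
      aFac <- exp(stats::rnorm(1L, 0, animalSdLog))
      aApc0 <- 2 * exp(stats::rnorm(1L, 0, 0.05))  # per-animal APC level
      tMin <- 0
      for (s in seq_along(stages)) {
        nTr <- if (stages[s] == "baseline") design@baselineTrials
               else design@trialsPerStep
        if (s > 1L) tMin <- tMin + design@interInfusionMin
        for (tr in seq_len(nTr)) {
          if (tr > 1L) tMin <- tMin + design@interTrialMin
          mult <- stageMult(g, stages[s]) * aFac *
            exp(stats::rnorm(1L, 0, trialSdLog))
          rows[[length(rows) + 1L]] <- data.frame(
            animal = animalId, group = design@groupNames[g],
            stage = stages[s], trial = tr, tStartMin = tMin,
            gainMult = mult, stringsAsFactors = FALSE)
          traces[[length(traces) + 1L]] <- simulateTrialTraces(
            hemo, protocol, gainMult = mult, rateHz = traceRateHz,
            baseApcPercent = aApc0)
          if (renderVideo) {
            tis <- makeTissue(seed + animalId, 64, 64)
            hemoTr <- hemo
            hemoTr@stimApcGain <- 1 + (hemo@stimApcGain - 1) * mult
            videos[[length(videos) + 1L]] <-
              simulateTrial(tis, hemoTr, protocol,
                            seed = seed + 1000L * animalId + tr)
          }
        }
      }
    }
  }
  schedule <- do.call(rbind, rows)
  schedule$stage <- factor(schedule$stage, levels = stages)

  gt <- expand.grid(group = design@groupNames, stage = stages,
                    stringsAsFactors = FALSE)
  gt$gainMult <- mapply(stageMult, match(gt$group, design@groupNames),
                        gt$stage)
  gt$stimApcGain <- 1 + (hemo@stimApcGain - 1) * gt$gainMult

  ds <- new("ExperimentDataset", schedule = schedule, traces = traces,
            groundTruth = gt, design = design, protocol = protocol,
            hemo = hemo)
  if (renderVideo) attr(ds, "videos") <- videos
  ds
}
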