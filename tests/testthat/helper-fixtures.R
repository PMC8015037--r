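# Shared fixtures, built in code and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# short no-stimulation protocol at desk-scale frame rate
quietProtocol <- function(preS = 6, fps = 50)
  TrialProtocol(preS = preS, stimS = 0, postS = 0, frameRateHz = fps)

# hemodynamics with everything switched off except the heartbeat;
# ... overrides the quiet defaults
quietHemo <- function(...) {
  args <- utils::modifyList(
    list(stimApcGain = 1, stimVolumeDrop = 0, motionAmplitudePx = 0,
         noiseSdCounts = 0, abpDipFrac = 0, hrDipFrac = 0),
    list(...))
  do.call(HemoDynamicsSpec, args)
}

# origin of a 3 x 3 ROI lying entirely inside an artery
allArteryRoi <- function(tissue) {
  m <- vesselMask(tissue) == 1L
  for (r in seq_len(nrow(m) - 2L)) for (cc in seq_len(ncol(m) - 2L))
    if (all(m[r:(r + 2L), cc:(cc + 2L)])) return(c(r, cc))
  stop("no all-artery 3 x 3 ROI in this tissue")
}

# origin of a 3 x 3 ROI lying entirely in background tissue
allBackgroundRoi <- function(tissue) {
  m <- vesselMask(tissue) == 0L
  for (r in seq_len(nrow(m) - 2L)) for (cc in seq_len(ncol(m) - 2L))
    if (all(m[r:(r + 2L), cc:(cc + 2L)])) return(c(r, cc))
  stop("no all-background 3 x 3 ROI")
}

# cached small clean trial: 64 x 64, 6 s @ 50 fps, no stimulation/noise
cleanSim <- function() fixture("cleanSim", function() {
  tis <- makeTissue(1, 64, 64)
  sim <- simulateTrial(tis, quietHemo(), quietProtocol(), seed = 11)
  list(tissue = tis, sim = sim)
})

# cached stimulated desk-scale trial with noise and motion (full defaults)
stimSim <- function() fixture("stimSim", function() {
  tis <- makeTissue(2, 120, 188)
  pr <- TrialProtocol(preS = 10, stimS = 8, postS = 18, frameRateHz = 50)
  sim <- simulateTrial(tis, HemoDynamicsSpec(), pr, seed = 7)
  list(tissue = tis, protocol = pr, sim = sim)
})

# null experiment generators used for statistical calibration.
# stimulated = TRUE: the stimulation response is present but identical in
# distribution at every stage and in every group (null for the
# across-stage Friedman and between-group Kruskal-Wallis tests);
# stimulated = FALSE: no stimulation effect at all (null for the
# within-trial pre/post Wilcoxon contrast).
nullExperiment <- function(seed, nPerGroup = 8L, traceRateHz = 4,
                           stimulated = TRUE) {
  des <- ExperimentDesign(nAnimals = rep(nPerGroup, 3L),
                          drugEffect = matrix(1, 3L, 3L),
                          timeDriftPerStep = 1)
  hemo <- if (stimulated) HemoDynamicsSpec() else
    HemoDynamicsSpec(stimApcGain = 1, stimVolumeDrop = 0,
                     abpDipFrac = 0, hrDipFrac = 0)
  simulateExperiment(des, hemo = hemo, seed = seed,
                     traceRateHz = traceRateHz)
}
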