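# Synthetic-data generator: tissue construction, trial forward model,
# experiment schedules.

test_that("tissue generation is deterministic and seed-sensitive", {
  t1 <- makeTissue(1, 120, 188)
  t2 <- makeTissue(1, 120, 188)
  t3 <- makeTissue(2, 120, 188)
  expect_identical(vesselMask(t1), vesselMask(t2))
  expect_identical(baselineIntensity(t1), baselineIntensity(t2))
  expect_false(identical(vesselMask(t1), vesselMask(t3)))
})

test_that("tissue construction constraints hold", {
  for (seed in 1:3) {
    tis <- makeTissue(seed, 96, 140)
    m <- vesselMask(tis)
    fArt <- mean(m == 1L)
    expect_gt(fArt, 0)
    expect_lt(fArt, 0.5)
    expect_gt(mean(m == 2L), 0)
    # arteries and veins cross the field: present in every column
    expect_true(all(colSums(m == 1L) > 0))
    expect_true(all(colSums(m == 2L) > 0))
    expect_true(all(baselineIntensity(tis) >= 0 &
                      baselineIntensity(tis) <= 1023))
    # electrodes inside the image and adjacent to an artery
    e <- electrodeXY(tis)
    art <- which(m == 1L, arr.ind = TRUE)
    dmin <- min(sqrt((art[, 1] - e[1, 1])^2 + (art[, 2] - e[1, 2])^2))
    expect_lt(dmin, 8)
  }
  expect_error(makeTissue(1, 40, 120), "48")
})

test_that("trial simulation is deterministic and respects the bit depth", {
  tis <- makeTissue(3, 64, 64)
  pr <- TrialProtocol(preS = 2, stimS = 1, postS = 1, frameRateHz = 50)
  s1 <- simulateTrial(tis, HemoDynamicsSpec(), pr, seed = 5)
  s2 <- simulateTrial(tis, HemoDynamicsSpec(), pr, seed = 5)
  expect_identical(videoFrames(s1@video), videoFrames(s2@video))
  expect_identical(peakTimes(s1@rpeaks), peakTimes(s2@rpeaks))
  expect_identical(s1@ecg@signalMv, s2@ecg@signalMv)
  expect_true(all(videoFrames(s1@video) >= 0 &
                    videoFrames(s1@video) <= 1023))
})

test_that("R-peak count follows the programmed heart rate", {
  # fixed R-R at 413 bpm over 120 s: floor(120 * 413 / 60) +- 1 peaks
  hemo <- quietHemo(hrVariability = 0)
  pr <- TrialProtocol(frameRateHz = 100)
  set.seed(1)
  rp <- generateRPeaks(120, hemo, pr)
  expect_lte(abs(length(peakTimes(rp)) - floor(120 * 413 / 60)), 1)
  expect_true(all(diff(peakTimes(rp)) > 0))
})

test_that("no-stimulation null: frames vary only with the cardiac cycle", {
  cs <- cleanSim()
  X <- videoFrames(cs$sim@video)
  # temporal mean over whole recording equals baseline (zero-mean template)
  err <- abs(apply(X, c(1, 2), mean) - baselineIntensity(cs$tissue))
  expect_lt(max(err) / mean(baselineIntensity(cs$tissue)), 0.005)
  # per-pixel range is bounded by the injected pulse amplitude
  aMax <- max(pulsatilityMap(cs$tissue))
  rng <- apply(X, c(1, 2), function(v) diff(range(v)))
  expect_lt(max(rng / baselineIntensity(cs$tissue)), aMax * 1.2)
})

test_that("injected pixel amplitude equals pulsatility x gain exactly", {
  # noise- and motion-free: max-min of I/B over a cycle = a * g * (max c - min c)
  cs <- cleanSim()
  X <- videoFrames(cs$sim@video)
  roi <- allArteryRoi(cs$tissue)
  px <- X[roi[1], roi[2], ]
  B <- baselineIntensity(cs$tissue)[roi[1], roi[2]]
  # sample the template densely: amplitude must match to sampling accuracy
  expect_equal(diff(range(px)) / B, 0.02,
               tolerance = 0.06)
})

test_that("pixel AC is phase-locked to the generated R-peaks", {
  cs <- cleanSim()
  X <- videoFrames(cs$sim@video)
  roi <- allArteryRoi(cs$tissue)
  px <- X[roi[1], roi[2], ]
  fps <- frameRate(cs$sim@video)
  tF <- frameTimes(cs$sim@video)
  rt <- peakTimes(cs$sim@rpeaks)
  rrMed <- median(diff(rt))
  knots <- c(rt[1] - rrMed, rt, rt[length(rt)] + rrMed)
  phase <- approx(knots, seq_along(knots) - 1, xout = tF, rule = 2)$y %% 1
  injected <- cardiacTemplate(phase)
  ac <- px - mean(px)
  # best lag of the cross-correlation must be 0 +- 1 frame
  lags <- -3:3
  cors <- vapply(lags, function(l) {
    n <- length(ac)
    idx <- seq_len(n - abs(l))
    if (l >= 0) cor(ac[idx + l], injected[idx]) else cor(ac[idx], injected[idx - l])
  }, numeric(1))
  expect_lte(abs(lags[which.max(cors)]), 1)
  expect_gt(max(cors), 0.95)
})

test_that("frame clipping beyond the bit depth is counted and warned", {
  tis <- makeTissue(4, 64, 64)
  b <- baselineIntensity(tis)
  b[b > 1010] <- 1010
  tis@baselineIntensity <- b + (1020 - max(b))  # push close to the ceiling
  pr <- TrialProtocol(preS = 1, stimS = 0, postS = 0, frameRateHz = 50)
  expect_warning(
    sim <- simulateTrial(tis, quietHemo(noiseSdCounts = 10), pr, seed = 1),
    "clipped")
  expect_gt(sim@clippedCount, 0L)
  expect_lte(max(videoFrames(sim@video)), 1023)
})

test_that("the default design yields 384 trials with the printed timeline", {
  ds <- simulateExperiment(ExperimentDesign(), seed = 1)
  sch <- trialSchedule(ds)
  expect_equal(nrow(sch), 384L)
  expect_equal(length(unique(sch$animal)), 32L)
  expect_equal(trialDuration(TrialProtocol()), 120)
  # schedule honors 10-min inter-trial and 30-min inter-infusion spacing
  one <- sch[sch$animal == 1L, ]
  expect_equal(diff(one$tStartMin[one$stage == "baseline"]), c(10, 10))
  lastBase <- max(one$tStartMin[one$stage == "baseline"])
  firstStep <- min(one$tStartMin[one$stage == "step1"])
  expect_equal(firstStep - lastBase, 30)
})

test_that("drug effects multiply the stimulated response as programmed", {
  # isolate the drug multipliers: no time drift, no biological variability
  des <- ExperimentDesign(nAnimals = c(2L, 2L, 2L),
                          drugEffect = rbind(c(1, 1, 1),
                                             c(0.8, 0.62, 0.5),
                                             c(0.8, 0.6, 0.4)),
                          timeDriftPerStep = 1)
  ds <- simulateExperiment(des, seed = 2, animalSdLog = 0, trialSdLog = 0)
  gt <- groundTruthEffects(ds)
  sal <- gt$gainMult[gt$group == "saline"]
  expect_equal(sal, rep(1, 4))  # identity multiplier path
  sum3 <- gt$stimApcGain[gt$group == "sumatriptan"]
  expect_true(all(diff(sum3) < 0))  # monotone decreasing stimulated APC
  # and the schedule's per-trial multipliers match the table
  sch <- trialSchedule(ds)
  m <- tapply(sch$gainMult[sch$group == "sumatriptan"],
              droplevels(sch$stage[sch$group == "sumatriptan"]), mean)
  expect_equal(as.numeric(m), c(1, 0.8, 0.6, 0.4), tolerance = 1e-10)
})

test_that("trace-level trial simulator reflects the programmed kinetics", {
  pr <- TrialProtocol()
  hemo <- HemoDynamicsSpec()
  set.seed(3)
  tr <- simulateTrialTraces(hemo, pr, gainMult = 1, rateHz = 10,
                            noise = list(apcRel = 0, oisAbs = 0,
                                         abpAbs = 0, hrAbs = 0))
  # pre-stimulation levels
  expect_equal(mean(tr$apc[tr$t < 20]), 2, tolerance = 1e-9)
  expect_equal(mean(tr$ois[tr$t < 20]), 100, tolerance = 1e-9)
  # APC peaks before OIS (faster onset), both peak in/after stimulation
  expect_lt(tr$t[which.max(tr$apc)], tr$t[which.max(tr$ois)] + 1e-9)
  # ABP dips during stimulation and recovers fast
  expect_lt(min(tr$abp), 72 * 0.95)
  expect_gt(mean(tr$abp[tr$t > 60]), 72 * 0.99)
})
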