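# Big-ROI selection, normalization and integral response metrics.

test_that("a uniquely bright block is selected first", {
  vals <- matrix(1, 30, 30)
  vals[10:18, 12:20] <- 5           # one bright 27 x 27 px (9 x 9 tile) block
  m <- new("APCMap", values = vals, mask = matrix(TRUE, 30, 30),
           roiPx = 3L, timestampS = 30)
  sel <- selectBigRois(m, electrodeXY = rbind(c(1, 1), c(2, 2)), k = 3)
  expect_equal(unname(roiOrigins(sel)[1, ]), c((10 - 1) * 3 + 1, (12 - 1) * 3 + 1))
})

test_that("ROI selection is deterministic and non-overlapping on ties", {
  vals <- matrix(1, 30, 30)
  m <- new("APCMap", values = vals, mask = matrix(TRUE, 30, 30),
           roiPx = 3L, timestampS = 30)
  sel <- selectBigRois(m, electrodeXY = rbind(c(1, 1), c(80, 80)), k = 6)
  o <- roiOrigins(sel)
  # row-major tie-break: first ROI at the origin
  expect_equal(unname(o[1, ]), c(1L, 1L))
  # pairwise non-overlap
  for (i in 1:5) for (j in (i + 1):6)
    expect_true(abs(o[i, 1] - o[j, 1]) >= 27 || abs(o[i, 2] - o[j, 2]) >= 27)
  expect_equal(sum(representativeRois(sel)), 2L)
  expect_error(selectBigRois(m, rbind(c(1, 1), c(2, 2)), k = 50), "disjoint")
})

test_that("representative ROIs sit next to the electrodes over arteries", {
  ss <- stimSim()
  m <- apcMap(ss$sim@video, ss$sim@rpeaks,
              atTimeS = ss$protocol@preS + ss$protocol@stimS / 2)
  sel <- selectBigRois(m, electrodeXY(ss$tissue))
  e <- electrodeXY(ss$tissue)
  reps <- which(representativeRois(sel))
  centers <- roiOrigins(sel)[reps, , drop = FALSE] + 13
  for (i in seq_len(nrow(centers))) {
    dmin <- min(sqrt((centers[i, 1] - e[, 1])^2 + (centers[i, 2] - e[, 2])^2))
    expect_lt(dmin, 60)
  }
  # representative ROIs contain artery pixels
  vm <- vesselMask(ss$tissue)
  for (i in reps) {
    o <- roiOrigins(sel)[i, ]
    expect_gt(sum(vm[o[1]:(o[1] + 26), o[2]:(o[2] + 26)] == 1L), 0)
  }
})

test_that("normalization pins the pre-stimulation mean at exactly 100%", {
  pr <- TrialProtocol()
  t <- seq(0, 119.9, by = 0.1)
  # constant trace -> constant 100%
  ntC <- normalizeTrace(t, rep(3.7, length(t)), "APC", pr)
  expect_true(all(traceValues(ntC) == 100))
  # doubling during stimulation -> 200% there
  v <- ifelse(t >= 20 & t < 35, 2, 1) * 5
  ntD <- normalizeTrace(t, v, "APC", pr)
  expect_equal(unique(traceValues(ntD)[t >= 20 & t < 35]), 200)
  # exactness of the pre-stimulation mean for arbitrary positive traces
  set.seed(31)
  for (r in 1:5) {
    vr <- exp(rnorm(length(t), 0, 0.3)) + 0.5
    nt <- normalizeTrace(t, vr, "APC", pr)
    expect_equal(mean(traceValues(nt)[t < 20]), 100, tolerance = 1e-12)
  }
  expect_error(normalizeTrace(t, rep(-1, length(t)), "APC", pr),
               "non-positive")
})

test_that("a synthetic ABP dip normalizes to the programmed minimum", {
  set.seed(33)
  tr <- simulateTrialTraces(HemoDynamicsSpec(abpDipFrac = 0.10),
                            TrialProtocol(),
                            noise = list(apcRel = 0, oisAbs = 0,
                                         abpAbs = 0.2, hrAbs = 0))
  nt <- normalizeTrace(tr$t, tr$abp, "ABP", TrialProtocol())
  expect_equal(min(traceValues(nt)), 90, tolerance = 0.01)
})

test_that("fixed-window integral follows the trapezoid arithmetic", {
  pr <- TrialProtocol()
  t <- seq(0, 119.5, by = 0.5)
  flat <- normalizeTrace(t, rep(2, length(t)), "APC", pr)
  expect_equal(integralStim(flat, pr), 0)
  # constant 120% during the whole window: 20% x 15 s = 300 %.s
  v <- ifelse(t >= 20 & t <= 35.5, 1.2, 1)
  step <- new("NormalizedTrace", parameter = "APC", t = t, values = 100 * v,
              preStimSD = 0, preS = 20)
  expect_equal(integralStim(step, pr), 300, tolerance = 0.01)
  # gaps inside the window are rejected
  keep <- !(t > 25 & t < 27)
  gappy <- new("NormalizedTrace", parameter = "APC", t = t[keep],
               values = rep(100, sum(keep)), preStimSD = 0, preS = 20)
  expect_error(integralStim(gappy, pr), "gap")
})

test_that("noise-free APC integral matches the closed-form kinetics", {
  pr <- TrialProtocol()
  hemo <- HemoDynamicsSpec()
  set.seed(35)
  tr <- simulateTrialTraces(hemo, pr, rateHz = 20,
                            noise = list(apcRel = 0, oisAbs = 0,
                                         abpAbs = 0, hrAbs = 0))
  nt <- normalizeTrace(tr$t, tr$apc, "APC", pr)
  expect_equal(integralStim(nt, pr), integralStimAnalytic(hemo, pr),
               tolerance = 0.05)
})

test_that("trapezoid integrals are additive across subwindows", {
  pr <- TrialProtocol()
  set.seed(37)
  tr <- simulateTrialTraces(HemoDynamicsSpec(), pr)
  nt <- normalizeTrace(tr$t, tr$apc, "APC", pr)
  ia <- integralAdaptive(nt, pr)
  part1 <- integralStim(nt, pr)                       # [20, 35]
  part2 <- ippg:::.integralExcess(nt@t, nt@values, 35, ia$endS)
  expect_equal(part1 + part2, ia$integral, tolerance = 1e-9)
})

test_that("the 2-SD return point lands where constructed", {
  pr <- TrialProtocol()
  t <- seq(0, 119.9, by = 0.1)
  set.seed(39)
  noise <- rnorm(length(t), 0, 0.5)
  v <- 100 + noise
  v[t >= 20 & t < 50] <- v[t >= 20 & t < 50] + 30  # step back at 50 s
  nt <- normalizeTrace(t, v, "APC", pr)
  ia <- integralAdaptive(nt, pr)
  expect_false(ia$truncated)
  expect_equal(ia$endS, 50, tolerance = 1.2)  # within the hold window
  # a never-returning trace truncates at the trial end
  v2 <- 100 + noise + ifelse(t >= 20, 30, 0)
  nt2 <- normalizeTrace(t, v2, "APC", pr)
  ia2 <- integralAdaptive(nt2, pr)
  expect_true(ia2$truncated)
  expect_equal(ia2$endS, max(t))
})

test_that("default kinetics return to baseline within 40-90 s", {
  pr <- TrialProtocol()
  set.seed(41)
  tr <- simulateTrialTraces(HemoDynamicsSpec(), pr)
  nt <- normalizeTrace(tr$t, tr$apc, "APC", pr)
  ia <- integralAdaptive(nt, pr)
  expect_false(ia$truncated)
  expect_gte(ia$endS, 40)
  expect_lte(ia$endS, 90)
})

test_that("baseline normalization divides by the animal's baseline mean", {
  df <- data.frame(animal = rep(1:2, each = 4),
                   stage = rep(c("baseline", "baseline", "baseline",
                                 "step1"), 2),
                   integral = c(2, 2, 2, 3, 4, 4, 4, 2))
  out <- baselineNormalize(df)
  expect_equal(out$normIntegral[out$animal == 1],
               c(1, 1, 1, 1.5))
  expect_equal(out$normIntegral[out$animal == 2],
               c(1, 1, 1, 0.5))
  # non-positive baseline mean excludes the animal
  df$integral[1:3] <- 0
  expect_warning(out2 <- baselineNormalize(df), "non-positive")
  expect_false(1 %in% out2$animal)
})

test_that("integral_stim strictly increases with the injected gain", {
  pr <- TrialProtocol()
  ints <- vapply(c(1.1, 1.3, 1.5, 1.8), function(g) {
    set.seed(43)
    tr <- simulateTrialTraces(HemoDynamicsSpec(stimApcGain = g), pr,
                              noise = list(apcRel = 0, oisAbs = 0,
                                           abpAbs = 0, hrAbs = 0))
    integralStim(normalizeTrace(tr$t, tr$apc, "APC", pr), pr)
  }, numeric(1))
  expect_true(all(diff(ints) > 0))
})

test_that("triple baseline trials are reproducible within noise", {
  ds <- simulateExperiment(ExperimentDesign(nAnimals = c(4L, 4L, 4L)),
                           seed = 45, trialSdLog = 0.05)
  rt <- responseTable(ds, parameters = "apc")
  base <- rt[rt$stage == "baseline", ]
  for (a in unique(base$animal)) {
    ints <- base$integralAdaptive[base$animal == a]
    spread <- diff(range(ints)) / mean(ints)
    expect_lt(spread, 3 * 0.20)   # ~3 x the trial-level variability
  }
})
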