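# Cardiac-gated PPG extraction: R-peak detection, AC/DC waveforms,
# ensemble-averaged pulses, APC and APC maps.

test_that("R-peak detection counts the programmed beats", {
  hemo <- quietHemo()
  pr <- TrialProtocol()
  set.seed(13)
  rp <- generateRPeaks(60, hemo, pr)
  ecg <- synthesizeECG(rp, 60, rateHz = 1000)
  det <- detectRPeaks(ecg)
  nTrue <- length(peakTimes(rp))
  expect_lte(abs(length(peakTimes(det)) - nTrue), 2)
  expect_lte(abs(nTrue - 413), 2)   # 413 bpm over 60 s
  # detected times align with ground truth within 5 ms
  matched <- vapply(peakTimes(det), function(tp)
    min(abs(peakTimes(rp) - tp)), numeric(1))
  expect_lt(median(matched), 0.005)
})

test_that("provided R-peak files pass through with a monotonicity check", {
  path <- withr::local_tempfile(fileext = ".csv")
  rp <- RPeakSeries(c(0.1, 0.25, 0.4))
  writeRPeaksCsv(rp, path)
  back <- readRPeaksCsv(path)
  expect_equal(peakTimes(back), c(0.1, 0.25, 0.4))
  expect_equal(back@source, "provided")
  writeLines(c("time_s", "0.4", "0.2"), path)
  expect_error(readRPeaksCsv(path), "increasing")
})

test_that("a missed beat shows up as a flagged double-length gap", {
  set.seed(14)
  rp <- generateRPeaks(20, quietHemo(hrVariability = 0.01),
                       TrialProtocol())
  tms <- peakTimes(rp)
  tms <- tms[-25]                      # remove one beat
  ecg <- synthesizeECG(RPeakSeries(tms), 20, rateHz = 1000)
  det <- detectRPeaks(ecg)
  gaps <- flagRRGaps(det)
  expect_equal(sum(gaps), 1L)
  rr <- diff(peakTimes(det))
  expect_equal(rr[which(gaps)] / median(rr), 2, tolerance = 0.1)
})

test_that("flat ECG yields an empty detection", {
  ecg <- ECGTrace(rep(0.3, 5000), rateHz = 1000)
  expect_length(peakTimes(detectRPeaks(ecg)), 0L)
})

test_that("constant video has identically zero AC/DC", {
  X <- array(500, dim = c(8, 8, 200))
  vid <- VideoRecording(X, frameRate = 50)
  rp <- RPeakSeries(seq(0.1, 3.9, by = 0.145))
  w <- extractWaveform(vid, c(3, 3), rp)
  expect_true(all(w@acOverDc == 0))
  expect_true(w@valid)
  expect_error(extractWaveform(vid, c(7, 7), rp), "inside")
})

test_that("sinusoidal modulation amplitude is recovered analytically", {
  # raw(t) = B (1 + A sin wt): max - min of ac/dc ~ 2A
  fps <- 100; A <- 0.02; fHz <- 7
  t <- (0:999) / fps
  raw <- 600 * (1 + A * sin(2 * pi * fHz * t))
  X <- array(rep(raw, each = 9), dim = c(3, 3, 1000))
  vid <- VideoRecording(X, frameRate = fps)
  rp <- RPeakSeries(seq(0.05, 9.9, by = 1 / fHz))
  w <- extractWaveform(vid, c(1, 1), rp)
  expect_equal(max(w@acOverDc) - min(w@acOverDc), 2 * A,
               tolerance = 0.05)
  mp <- meanPulse(w, rp)
  expect_equal(apc(mp), 100 * 2 * A, tolerance = 0.05)
})

test_that("injected artery pulsatility is recovered within 10%", {
  cs <- cleanSim()
  w <- extractWaveform(cs$sim@video, allArteryRoi(cs$tissue), cs$sim@rpeaks)
  mp <- meanPulse(w, cs$sim@rpeaks)
  expect_equal(apc(mp), 2.0, tolerance = 0.10)
})

test_that("mean pulse of identical cycles equals one resampled cycle", {
  fps <- 100; rr <- 0.2
  t <- (0:599) / fps
  phase <- (t / rr) %% 1
  vals <- 0.01 * cardiacTemplate(phase)
  w <- new("PPGWaveform", roiOrigin = c(1L, 1L), t = t, raw = vals,
           dc = rep(1, 600), acOverDc = vals, valid = TRUE)
  rp <- RPeakSeries(seq(0.2, 4.6, by = rr) + 1e-9)
  mp10 <- meanPulse(w, rp, startCycle = 2, nCycles = 10)
  mp1 <- meanPulse(w, rp, startCycle = 6, nCycles = 1)
  expect_equal(mp10@values, mp1@values, tolerance = 1e-9)
})

test_that("averaging 10 cycles reduces independent noise by about sqrt(10)", {
  fps <- 100; rr <- 0.2; sigma <- 0.01
  t <- (0:1999) / fps
  nrep <- 40
  resid <- matrix(0, nrep, 2)
  set.seed(15)
  for (r in seq_len(nrep)) {
    noise <- rnorm(length(t), 0, sigma)
    w <- new("PPGWaveform", roiOrigin = c(1L, 1L), t = t, raw = noise,
             dc = rep(1, length(t)), acOverDc = noise, valid = TRUE)
    rp <- RPeakSeries(seq(0, 19, by = rr) + 1e-9)
    mp <- meanPulse(w, rp, nCycles = 10, method = "linear")
    resid[r, ] <- c(sd(mp@values), sigma)
  }
  # residual SD ~ sigma / sqrt(10), with the linear-interpolation variance
  # factor E[(1-u)^2 + u^2] = 0.68 for this phase/frame grid
  expect_equal(mean(resid[, 1]), sigma * sqrt(0.68) / sqrt(10),
               tolerance = 0.1)
})

test_that("mean-pulse errors are informative", {
  cs <- cleanSim()
  w <- extractWaveform(cs$sim@video, allArteryRoi(cs$tissue), cs$sim@rpeaks)
  expect_error(meanPulse(w, cs$sim@rpeaks, startCycle = 1000), "cycles")
})

test_that("APC arithmetic: constant pulse 0, symmetric pulse 2%", {
  mpFlat <- new("MeanPulse", phase = (0:49) / 50, values = rep(0.3, 50),
                nCycles = 10L, windowCenterS = 1)
  expect_equal(apc(mpFlat), 0)
  mpSym <- new("MeanPulse", phase = (0:49) / 50,
               values = rep(c(-0.01, 0.01), 25), nCycles = 10L,
               windowCenterS = 1)
  expect_equal(apc(mpSym), 2.0)
})

test_that("APC is invariant to global gain and AC sign flips", {
  cs <- cleanSim()
  roi <- allArteryRoi(cs$tissue)
  rp <- cs$sim@rpeaks
  vid <- cs$sim@video
  a0 <- apc(meanPulse(extractWaveform(vid, roi, rp), rp))
  vid2 <- VideoRecording(videoFrames(vid) * 3.7, frameRate = frameRate(vid))
  a2 <- apc(meanPulse(extractWaveform(vid2, roi, rp), rp))
  expect_equal(a2, a0, tolerance = 1e-12)
  # sign flip of the AC convention
  w <- extractWaveform(vid, roi, rp)
  wFlip <- new("PPGWaveform", roiOrigin = w@roiOrigin, t = w@t,
               raw = w@raw, dc = w@dc, acOverDc = -w@acOverDc,
               valid = TRUE)
  expect_equal(apc(meanPulse(wFlip, rp)), a0, tolerance = 1e-12)
})

test_that("sliding the 10-cycle window barely changes stationary APC", {
  cs <- cleanSim()
  w <- extractWaveform(cs$sim@video, allArteryRoi(cs$tissue), cs$sim@rpeaks)
  ser <- apcSeries(w, cs$sim@rpeaks)
  expect_gt(nrow(ser), 10)
  expect_lt(max(abs(ser$apc - median(ser$apc))), 0.05 * median(ser$apc))
})

test_that("recovered APC is monotone in the injected amplitude", {
  pr <- quietProtocol()
  recover <- function(a) {
    tis <- makeTissue(1, 64, 64, arteryPulsatility = a,
                      veinPulsatility = a / 4)
    sim <- simulateTrial(tis, quietHemo(noiseSdCounts = 2), pr, seed = 17)
    w <- extractWaveform(sim@video, allArteryRoi(tis), sim@rpeaks)
    apc(meanPulse(w, sim@rpeaks))
  }
  # max - min is positively biased by sensor noise; measure the noise
  # floor with a (near-)zero-amplitude control and allow it on top of the
  # 10% estimator tolerance
  floorApc <- recover(1e-6)
  expect_lt(floorApc, 0.3)
  inj <- c(0.5, 1, 2, 4)
  rec <- vapply(inj / 100, recover, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_true(all(abs(rec - inj) < 0.10 * inj + floorApc))
})

test_that("APC map geometry and artery/vein contrast are correct", {
  cs <- cleanSim()
  m <- apcMap(cs$sim@video, cs$sim@rpeaks, atTimeS = 3)
  expect_equal(dim(mapValues(m)), c(64L %/% 3L, 64L %/% 3L))
  # median artery-tile APC exceeds median vein-tile APC
  vm <- vesselMask(cs$tissue)
  tileClass <- function(r, cc) {
    px <- vm[((r - 1) * 3 + 1):(r * 3), ((cc - 1) * 3 + 1):(cc * 3)]
    if (all(px == 1L)) "artery" else if (all(px == 2L)) "vein" else "mixed"
  }
  cls <- outer(seq_len(21), seq_len(21), Vectorize(tileClass))
  v <- mapValues(m)[, seq_len(21)]
  expect_gt(median(v[cls == "artery"]), median(v[cls == "vein"]))
  # 752 px width: 250 tile columns (2 residual pixel columns dropped)
  expect_equal(752L %/% 3L, 250L)
})

test_that("stimulation raises the APC map near the electrodes", {
  ss <- stimSim()
  rp <- ss$sim@rpeaks
  mPre <- apcMap(ss$sim@video, rp, atTimeS = 5)
  mStim <- apcMap(ss$sim@video, rp, atTimeS = ss$protocol@preS +
                    ss$protocol@stimS - 1)
  e <- electrodeXY(ss$tissue)
  rT <- pmax(1, (e[, 1] %/% 3)); cT <- pmax(1, (e[, 2] %/% 3))
  # 5 x 5 tile neighborhoods around both electrodes
  nb <- function(m) {
    v <- c()
    for (i in 1:2) {
      rs <- max(1, rT[i] - 2):min(nrow(mapValues(m)), rT[i] + 2)
      cs <- max(1, cT[i] - 2):min(ncol(mapValues(m)), cT[i] + 2)
      v <- c(v, mapValues(m)[rs, cs])
    }
    v
  }
  expect_gt(mean(nb(mStim), na.rm = TRUE), mean(nb(mPre), na.rm = TRUE))
})
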