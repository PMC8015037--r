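# Segment-wise gradient motion estimation and compensation.

test_that("segment grids tile the frame exactly", {
  g <- makeGrid(480, 752, 16)
  expect_equal(gridDim(g), c(30L, 47L))          # 1410 segments
  expect_true(all(g@rowSizes == 16L) && all(g@colSizes == 16L))

  g1 <- makeGrid(16, 16, 16)
  expect_equal(prod(gridDim(g1)), 1L)

  # 20 x 20: four segments, edge sizes 16x4, 4x16, 4x4
  g2 <- makeGrid(20, 20, 16)
  expect_equal(gridDim(g2), c(2L, 2L))
  expect_equal(g2@rowSizes, c(16L, 4L))
  expect_equal(g2@colSizes, c(16L, 4L))
  expect_equal(sum(outer(g2@rowSizes, g2@colSizes)), 400L)

  expect_error(makeGrid(0, 10), "positive")
})

# textured reference frame for shift experiments
texturedFrame <- function(h = 64, w = 64, seed = 9) {
  set.seed(seed)
  f <- matrix(stats::rnorm(h * w), h, w)
  f <- apply(f, 2, ippg:::gaussianSmooth, sigma = 2)
  f <- t(apply(f, 1, ippg:::gaussianSmooth, sigma = 2))
  500 + 300 * f / max(abs(f))
}

test_that("identical frames give zero offsets everywhere", {
  f <- texturedFrame()
  vid <- VideoRecording(array(rep(f, 3), dim = c(64, 64, 3)), frameRate = 50)
  grid <- makeGrid(64, 64)
  mf <- estimateOffsets(vid, grid)
  expect_true(all(mf@dx == 0) && all(mf@dy == 0))
  expect_false(any(mf@flagged))
})

test_that("a constructed 1 px shift is recovered within 0.15 px", {
  f <- texturedFrame()
  shifted <- ippg:::bilinearShift(f, 1.0, 0)
  vid <- VideoRecording(array(c(f, shifted), dim = c(64, 64, 2)),
                        frameRate = 50)
  grid <- makeGrid(64, 64)
  mf <- estimateOffsets(vid, grid)
  # interior segments (edge segments see replicated borders)
  dx <- mf@dx[2:3, 2:3, 2]; dy <- mf@dy[2:3, 2:3, 2]
  expect_true(all(abs(dx - 1.0) < 0.15))
  expect_true(all(abs(dy) < 0.15))

  shifted2 <- ippg:::bilinearShift(f, 0, -0.7)
  vid2 <- VideoRecording(array(c(f, shifted2), dim = c(64, 64, 2)),
                         frameRate = 50)
  mf2 <- estimateOffsets(vid2, grid)
  expect_true(all(abs(mf2@dy[2:3, 2:3, 2] + 0.7) < 0.15))
})

test_that("texture-free segments are flagged and carry zero offset", {
  f <- texturedFrame()
  f[1:20, 1:20] <- 400   # uniform over the first segment plus its margin
  g <- matrix(400, 64, 64)       # fully uniform frame
  vid <- VideoRecording(array(c(f, f + 1), dim = c(64, 64, 2)),
                        frameRate = 50)
  mf <- estimateOffsets(vid, makeGrid(64, 64))
  expect_true(mf@flagged[1, 1, 2])
  expect_equal(mf@dx[1, 1, 2], 0)

  vidU <- VideoRecording(array(rep(g, 2), dim = c(64, 64, 2)),
                         frameRate = 50)
  expect_warning(mfU <- estimateOffsets(vidU, makeGrid(64, 64)),
                 "ill-conditioned")
  expect_true(all(mfU@flagged))
})

test_that("compensation with zero offsets is the identity", {
  cs <- cleanSim()
  vid <- cs$sim@video
  grid <- makeGrid(64, 64)
  d <- dim(videoFrames(vid))
  zero <- array(0, c(gridDim(grid), d[3]))
  mf <- new("MotionField", dx = zero, dy = zero,
            flagged = array(FALSE, dim(zero)), maxOffsetPx = 8,
            referenceFrame = 1L)
  out <- compensate(vid, mf, grid)
  expect_identical(videoFrames(out), videoFrames(vid))
})

test_that("compensation removes most variance of a pure-motion video", {
  f <- texturedFrame(64, 64)
  set.seed(21)
  nF <- 120
  path <- ippg:::gaussianSmooth(cumsum(rnorm(nF)), sigma = 8)
  path <- 1.5 * (path - mean(path)) / max(abs(path - mean(path)))
  X <- array(0, c(64, 64, nF))
  for (i in seq_len(nF)) X[, , i] <- ippg:::bilinearShift(f, path[i], 0.5 * path[i])
  vid <- VideoRecording(X, frameRate = 50)
  mc <- motionCompensate(vid)
  vRaw <- mean(apply(X, c(1, 2), var))
  vMc <- mean(apply(videoFrames(mc$video), c(1, 2), var))
  expect_lt(vMc, 0.5 * vRaw)
})

test_that("offset estimation is local to each segment", {
  f <- texturedFrame()
  f2 <- f
  # perturb only the last segment block
  f2[49:64, 49:64] <- ippg:::bilinearShift(f, 2, 2)[49:64, 49:64]
  vid <- VideoRecording(array(c(f, f2), dim = c(64, 64, 2)), frameRate = 50)
  mf <- estimateOffsets(vid, makeGrid(64, 64))
  expect_equal(mf@dx[1:3, 1:3, 2], matrix(0, 3, 3))
  expect_false(mf@dx[4, 4, 2] == 0 && mf@dy[4, 4, 2] == 0)
})

test_that("compensation leaves motion-free pulsatile APC intact", {
  cs <- cleanSim()
  mc <- motionCompensate(cs$sim@video, rpeaks = cs$sim@rpeaks)
  roi <- allArteryRoi(cs$tissue)
  w0 <- extractWaveform(cs$sim@video, roi, cs$sim@rpeaks)
  w1 <- extractWaveform(mc$video, roi, cs$sim@rpeaks)
  a0 <- apc(meanPulse(w0, cs$sim@rpeaks))
  a1 <- apc(meanPulse(w1, cs$sim@rpeaks))
  expect_lt(abs(a1 - a0) / a0, 0.01)
})

test_that("compensation brings APC closer to ground truth under motion", {
  # same tissue and seed with and without motion; error measured over an
  # artery ROI against the injected 2% amplitude
  tis <- makeTissue(5, 96, 96)
  pr <- quietProtocol(preS = 6)
  hemoM <- quietHemo(motionAmplitudePx = 1.5, noiseSdCounts = 2)
  sim <- simulateTrial(tis, hemoM, pr, seed = 31)
  roi <- allArteryRoi(tis)
  injected <- 2.0
  apcOf <- function(video) {
    wave <- extractWaveform(video, roi, sim@rpeaks)
    apc(meanPulse(wave, sim@rpeaks))
  }
  errRaw <- abs(apcOf(sim@video) - injected)
  mc <- motionCompensate(sim@video, rpeaks = sim@rpeaks)
  errMc <- abs(apcOf(mc$video) - injected)
  expect_lt(errMc, errRaw)
})
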