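# Internal numerical helpers shared across modules.

# Clamp values into [lo, hi]; returns list(values, nClipped).
clipCounts <- function(x, lo = 0, hi = 1023) {
  n <- sum(x < lo | x > hi)
  x[x < lo] <- lo
  x[x > hi] <- hi
  list(values = x, nClipped = n)
}

# Shift image content by (dx, dy) pixels (dx = columns/x, dy = rows/y,
# positive = content moves right/down) using bilinear interpolation with
# edge replication: out(r, c) = in(r - dy, c - dx).
bilinearShift <- function(img, dx, dy) {
  h <- nrow(img); w <- ncol(img)
  rs <- seq_len(h) - dy
  cs <- seq_len(w) - dx
  r0 <- pmin(pmax(floor(rs), 1L), h); r1 <- pmin(r0 + 1L, h)
  c0 <- pmin(pmax(floor(cs), 1L), w); c1 <- pmin(c0 + 1L, w)
  fr <- pmin(pmax(rs - r0, 0), 1)
  fc <- pmin(pmax(cs - c0, 0), 1)
  # outer-product weights: rows vary with fr, columns with fc
  a <- img[r0, c0, drop = FALSE]; b <- img[r0, c1, drop = FALSE]
  d <- img[r1, c0, drop = FALSE]; e <- img[r1, c1, drop = FALSE]
  wr <- matrix(fr, h, w); wc <- matrix(fc, h, w, byrow = TRUE)
  (1 - wr) * ((1 - wc) * a + wc * b) + wr * ((1 - wc) * d + wc * e)
}

# Centered moving average of a vector with an odd window. Near the edges
# the window is slid (not shrunk) so it always spans a full window length:
# a shrinking window would cover a fraction of a cardiac cycle and leak
# heartbeat phase into the DC estimate of the first frames.
centeredMA <- function(x, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(x)
  if (window >= n) return(rep(mean(x), n))
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmin(pmax(seq_len(n) - half, 1L), n - window + 1L)
  hi <- lo + window - 1L
  (cs[hi + 1L] - cs[lo]) / window
}

# Column-wise centered moving average of a T x N matrix (same edge rule).
centeredMAMat <- function(X, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- nrow(X)
  if (window >= n)
    return(matrix(colMeans(X), n, ncol(X), byrow = TRUE))
  half <- (window - 1L) %/% 2L
  cs <- rbind(0, apply(X, 2L, cumsum))
  lo <- pmin(pmax(seq_len(n) - half, 1L), n - window + 1L)
  hi <- lo + window - 1L
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / window
}

# Odd frame count closest to a duration in seconds at a given rate.
oddWindowFrames <- function(durationS, rateHz) {
  w <- max(3L, as.integer(round(durationS * rateHz)))
  if (w %% 2L == 0L) w + 1L else w
}

# Smooth a vector with a Gaussian kernel (used for motion paths).
gaussianSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, k, sides = 2L))[(half + 1L):(half + n)]
}

# Resample uniformly sampled series at arbitrary query times.
# Y: nSeries x T matrix (rows are series sampled at t0 + (j-1) dt);
# returns nSeries x length(q). method "cubic" is a Catmull-Rom 4-tap
# kernel (C1, interpolating); "linear" the 2-tap hat. Indices are clamped
# at the ends (edge replication).
resampleUniform <- function(Y, t0, dt, q, method = c("cubic", "linear")) {
  method <- match.arg(method)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  nT <- ncol(Y); nS <- nrow(Y)
  x <- (q - t0) / dt + 1
  out <- matrix(0, nS, length(q))
  if (method == "linear") {
    i0 <- pmin(pmax(floor(x), 1L), nT - 1L)
    u <- pmin(pmax(x - i0, 0), 1)
    out <- Y[, i0, drop = FALSE] * rep(1 - u, each = nS) +
      Y[, i0 + 1L, drop = FALSE] * rep(u, each = nS)
  } else {
    i0 <- pmin(pmax(floor(x), 1L), nT - 1L)
    u <- pmin(pmax(x - i0, 0), 1)
    im <- pmax(i0 - 1L, 1L); i1 <- i0 + 1L; i2 <- pmin(i0 + 2L, nT)
    u2 <- u * u; u3 <- u2 * u
    wm <- (-u3 + 2 * u2 - u) / 2
    w0 <- (3 * u3 - 5 * u2 + 2) / 2
    w1 <- (-3 * u3 + 4 * u2 + u) / 2
    w2 <- (u3 - u2) / 2
    out <- Y[, im, drop = FALSE] * rep(wm, each = nS) +
      Y[, i0, drop = FALSE] * rep(w0, each = nS) +
      Y[, i1, drop = FALSE] * rep(w1, each = nS) +
      Y[, i2, drop = FALSE] * rep(w2, each = nS)
  }
  out
}
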