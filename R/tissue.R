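#' Generate a synthetic cranial-window tissue model
#'
#' Builds a field of view resembling green-light reflectance imaging through
#' a thinned skull: a smoothly varying parenchyma background with one or two
#' artery and vein paths crossing the field (vessels absorb green light and
#' appear darker; veins darker than arteries), class-wise fractional
#' pulsatilities (arteries pulse strongly with the cardiac cycle, veins
#' weakly, parenchyma faintly) and two stimulation electrodes placed
#' adjacent to an artery. Deterministic for a fixed seed.
#'
#' @param seed integer RNG seed.
#' @param heightPx,widthPx image dimensions, pixels (>= 48 each so a 27 x 27
#'   analysis window fits with margin).
#' @param pixelPitchUm micrometres per pixel.
#' @param arteryPulsatility,veinPulsatility,backgroundPulsatility fractional
#'   cardiac AC/DC amplitudes per pixel class.
#' @return a \linkS4class{TissueModel}.
#' @examples
#' tis <- makeTissue(1, 120, 188)
#' mean(vesselMask(tis) == 1)   # artery pixel fraction
#' @export
makeTissue <- function(seed, heightPx = 120L, widthPx = 188L,
                       pixelPitchUm = 21.676,
                       arteryPulsatility = 0.02, veinPulsatility = 0.005,
                       backgroundPulsatility = 0.003) {
  heightPx <- as.integer(heightPx); widthPx <- as.integer(widthPx)
  if (heightPx < 48L || widthPx < 48L)
    stop("image must be at least 48 x 48 px to host a 27 x 27 ROI")
  set.seed(as.integer(seed))

  h <- heightPx; w <- widthPx
  mask <- matrix(0L, h, w)

  # vessel paths: smooth horizontal traversals at distinct vertical bands
  drawVessel <- function(mask, label, centerRow, halfWidth, wobble) {
    path <- gaussianSmooth(cumsum(stats::rnorm(w, 0, wobble)), sigma = 8)
    path <- centerRow + path - mean(path)
    path <- pmin(pmax(path, halfWidth + 1), h - halfWidth)
    for (cc in seq_len(w)) {
      r0 <- max(1L, as.integer(floor(path[cc] - halfWidth)))
      r1 <- min(h, as.integer(ceiling(path[cc] + halfWidth)))
      mask[r0:r1, cc] <- label
    }
    mask
  }

  nArt <- if (h >= 100L) 2L else 1L
  nVein <- if (h >= 100L) 2L else 1L
  bands <- seq(0.15, 0.85, length.out = nArt + nVein) * h
  labels <- rep(c(1L, 2L), length.out = nArt + nVein)
  halfw <- c(1.6, 2.2)  # arteries slightly thinner than veins
  for (i in seq_along(bands))
    mask <- drawVessel(mask, labels[i], bands[i], halfw[labels[i]],
                       wobble = 0.8)

  # parenchyma background: smooth multiplicative texture around 620 counts
  tex <- matrix(stats::rnorm(h * w), h, w)
  tex <- apply(tex, 2L, gaussianSmooth, sigma = 4)
  tex <- t(apply(tex, 1L, gaussianSmooth, sigma = 4))
  tex <- tex / max(stats::sd(tex), 1e-12)
  base <- 620 * (1 + 0.05 * tex)
  base[mask == 1L] <- base[mask == 1L] * 0.75
  base[mask == 2L] <- base[mask == 2L] * 0.60
  base <- pmin(pmax(base, 0), 1023)

  # electrodes adjacent to an artery, near mid-field
  art <- which(mask == 1L, arr.ind = TRUE)
  target <- c(h / 2, w / 3)
  d2 <- (art[, 1] - target[1])^2 + (art[, 2] - target[2])^2
  anchor <- art[which.min(d2), ]
  off <- 4L
  e1 <- c(min(max(anchor[1] - off, 1L), h), anchor[2])
  e2 <- c(min(max(anchor[1] + off, 1L), h),
          min(max(anchor[2] + off, 1L), w))
  electrodes <- rbind(e1, e2)
  dimnames(electrodes) <- list(c("e1", "e2"), c("row", "col"))
  storage.mode(electrodes) <- "integer"

  new("TissueModel", vesselMask = mask, baselineIntensity = base,
      arteryPulsatility = arteryPulsatility,
      veinPulsatility = veinPulsatility,
      backgroundPulsatility = backgroundPulsatility,
      pixelPitchUm = pixelPitchUm, electrodeXY = electrodes)
}

#' Per-pixel pulsatility of a tissue model
#'
#' Expands the class-wise fractional amplitudes onto the pixel grid.
#'
#' @param tissue a \linkS4class{TissueModel}.
#' @return numeric matrix of fractional cardiac amplitudes.
#' @export
pulsatilityMap <- function(tissue) {
  a <- matrix(tissue@backgroundPulsatility, nrow(tissue@vesselMask),
              ncol(tissue@vesselMask))
  a[tissue@vesselMask == 1L] <- tissue@arteryPulsatility
  a[tissue@vesselMask == 2L] <- tissue@veinPulsatility
  a
}
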