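# Big-ROI selection, pre-stimulation normalization and integral response
# metrics (fixed 20-35 s window and adaptive 2-SD-return window).

#' Select the six big analysis ROIs on an APC map
#'
#' Greedy selection of \code{k} non-overlapping 27 x 27 px windows
#' maximizing mean APC on the map computed at the 10th second of
#' stimulation; ties are broken in row-major order. The two selected
#' windows nearest the stimulation electrodes are flagged representative
#' (ties go to the higher-APC window), mirroring the choice of
#' electrode-adjacent, artery-containing windows.
#'
#' @param map an \linkS4class{APCMap} (3 px tiles).
#' @param electrodeXY 2 x 2 matrix of electrode (row, col) pixel positions.
#' @param k number of ROIs (6).
#' @param roiPx ROI side in pixels (27; must be a multiple of the map tile).
#' @return a \linkS4class{BigROISelection}.
#' @export
selectBigRois <- function(map, electrodeXY, k = 6L, roiPx = 27L) {
  tile <- map@roiPx
  if (roiPx %% tile != 0L)
    stop("ROI side must be a multiple of the APC-map tile size")
  wT <- roiPx %/% tile
  V <- map@values
  V[!map@mask | !is.finite(V)] <- 0
  nTr <- nrow(V); nTc <- ncol(V)
  if (nTr < wT || nTc < wT) stop("frame too small to host a 27 x 27 px ROI")
  # window means via 2-d cumulative sums
  cs <- apply(apply(V, 2L, cumsum), 1L, cumsum)  # transposed double cumsum
  cs <- t(cs)
  csp <- matrix(0, nTr + 1L, nTc + 1L)
  csp[2:(nTr + 1L), 2:(nTc + 1L)] <- cs
  nWr <- nTr - wT + 1L; nWc <- nTc - wT + 1L
  wm <- (csp[(wT + 1L):(nTr + 1L), (wT + 1L):(nTc + 1L)] -
           csp[1:nWr, (wT + 1L):(nTc + 1L)] -
           csp[(wT + 1L):(nTr + 1L), 1:nWc] +
           csp[1:nWr, 1:nWc]) / (wT * wT)

  picks <- matrix(0L, 0L, 2L)
  meanApc <- numeric(0)
  avail <- matrix(TRUE, nWr, nWc)
  for (j in seq_len(k)) {
    if (!any(avail)) stop(sprintf("frame too small for %d disjoint ROIs", k))
    best <- max(wm[avail])
    cand <- which(wm == best & avail, arr.ind = TRUE)
    # row-major tie-break: smallest row, then smallest column
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    p <- cand[1, ]
    picks <- rbind(picks, p)
    meanApc <- c(meanApc, best)
    rBlk <- pmax(1L, p[1] - wT + 1L):pmin(nWr, p[1] + wT - 1L)
    cBlk <- pmax(1L, p[2] - wT + 1L):pmin(nWc, p[2] + wT - 1L)
    avail[rBlk, cBlk] <- FALSE
  }
  originsPx <- cbind((picks[, 1] - 1L) * tile + 1L,
                     (picks[, 2] - 1L) * tile + 1L)
  dimnames(originsPx) <- list(NULL, c("row", "col"))
  storage.mode(originsPx) <- "integer"

  centers <- originsPx + (roiPx - 1) / 2
  dmin <- vapply(seq_len(k), function(i) {
    min(sqrt((centers[i, 1] - electrodeXY[, 1])^2 +
               (centers[i, 2] - electrodeXY[, 2])^2))
  }, numeric(1))
  ord <- order(dmin, -meanApc)
  rep <- logical(k); rep[ord[1:2]] <- TRUE

  new("BigROISelection", origins = originsPx, representative = rep,
      roiPx = as.integer(roiPx), meanApc = meanApc)
}

#' Normalize a parameter trace to its pre-stimulation mean
#'
#' Values become percentages of the mean over the first \code{preS} seconds
#' of the trial, so the pre-stimulation phase averages exactly 100%.
#'
#' @param t sample times, seconds from trial start.
#' @param values raw parameter values (APC %, OIS-level, mmHg, bpm, ...).
#' @param parameter label: "APC", "OIS", "ABP" or "HR".
#' @param protocol a \linkS4class{TrialProtocol} (supplies preS).
#' @return a \linkS4class{NormalizedTrace}.
#' @export
normalizeTrace <- function(t, values, parameter = "APC",
                           protocol = TrialProtocol()) {
  pre <- t < protocol@preS
  if (sum(pre) < 2L) stop("pre-stimulation phase must contain >= 2 samples")
  m <- mean(values[pre])
  if (!is.finite(m) || m <= 0)
    stop("non-positive pre-stimulation mean; trial excluded")
  v <- 100 * values / m
  new("NormalizedTrace", parameter = parameter, t = as.numeric(t),
      values = v, preStimSD = stats::sd(v[pre]), preS = protocol@preS)
}

# common gap guard for the integral metrics
.checkGaps <- function(t, from, to) {
  inWin <- t >= from & t <= to
  if (sum(inWin) < 2L) stop("integration window not covered by the trace")
  dt <- diff(t)
  if (any(diff(t[inWin]) > 2 * median(dt) + 1e-12))
    stop("gap exceeding 2 sample intervals inside the integration window")
}

# trapezoid of (values - 100) over [from, to] with interpolated endpoints
.integralExcess <- function(t, values, from, to) {
  inWin <- t > from & t < to
  tt <- c(from, t[inWin], to)
  vv <- c(stats::approx(t, values, xout = from, rule = 2)$y,
          values[inWin],
          stats::approx(t, values, xout = to, rule = 2)$y)
  pracma::trapz(tt, vv - 100)
}

#' Fixed-window stimulation integral
#'
#' Trapezoidal integral of (value - 100%) over the stimulation phase
#' (20-35 s of the trial under the standard protocol), in percent-seconds.
#'
#' @param trace a \linkS4class{NormalizedTrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @return integral in percent-seconds.
#' @export
integralStim <- function(trace, protocol = TrialProtocol()) {
  from <- protocol@preS; to <- protocol@preS + protocol@stimS
  if (min(trace@t) > from || max(trace@t) < to)
    stop("trace does not cover the stimulation window")
  .checkGaps(trace@t, from, to)
  .integralExcess(trace@t, trace@values, from, to)
}

#' Adaptive integral to the 2-SD return
#'
#' Integrates (value - 100%) from stimulation onset (20 s) to the first
#' time, at or after the end of stimulation (35 s), at which the trace has
#' returned into the pre-stimulation band 100% +- 2 SD and stays there for
#' a sustained hold window (1 s by default, to avoid noise-triggered early
#' stops). A trace that never returns is integrated to the trial end and
#' flagged truncated. With a degenerate (zero) SD the band falls back to an
#' exact-equality tolerance of 1e-9.
#'
#' @param trace a \linkS4class{NormalizedTrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param holdS sustained-return hold window, seconds.
#' @return list(integral = percent-seconds, endS = integration end,
#'   truncated = logical).
#' @export
integralAdaptive <- function(trace, protocol = TrialProtocol(), holdS = 1) {
  from <- protocol@preS
  tEarliest <- protocol@preS + protocol@stimS
  t <- trace@t; v <- trace@values
  band <- 2 * trace@preStimSD
  if (!is.finite(band) || band <= 0) band <- 1e-9
  within <- abs(v - 100) <= band
  candIdx <- which(t >= tEarliest)
  endS <- max(t); truncated <- TRUE
  for (i in candIdx) {
    hold <- which(t >= t[i] & t <= t[i] + holdS)
    if (all(within[hold])) { endS <- t[i]; truncated <- FALSE; break }
  }
  .checkGaps(t, from, endS)
  list(integral = .integralExcess(t, v, from, endS), endS = endS,
       truncated = truncated)
}

#' Normalize integrals to the animal's baseline mean
#'
#' Divides every integral by the mean of the animal's three baseline-trial
#' integrals. Animals with a non-positive baseline mean are flagged and
#' excluded (their exclusion is recorded in the "excluded" attribute).
#'
#' @param df data.frame with at least columns \code{animal}, \code{stage}
#'   and \code{integral} ("baseline" marks baseline trials).
#' @return the data.frame with a \code{normIntegral} column; excluded
#'   animals (non-positive baseline mean) are dropped.
#' @export
baselineNormalize <- function(df) {
  stopifnot(all(c("animal", "stage", "integral") %in% names(df)))
  base <- tapply(df$integral[df$stage == "baseline"],
                 df$animal[df$stage == "baseline"], mean)
  bad <- names(base)[!is.finite(base) | base <= 0]
  if (length(bad) > 0L)
    warning(sprintf("excluding %d animal(s) with non-positive baseline mean",
                    length(bad)))
  keep <- !(as.character(df$animal) %in% bad)
  out <- df[keep, , drop = FALSE]
  out$normIntegral <- as.numeric(out$integral /
                                   base[as.character(out$animal)])
  attr(out, "excluded") <- bad
  out
}

#' Per-trial response metrics for a simulated experiment
#'
#' Normalizes every per-trial parameter trace of an
#' \linkS4class{ExperimentDataset} to its pre-stimulation mean and computes
#' the fixed-window and adaptive integral metrics, plus the OIS quality
#' gate per trial.
#'
#' @param dataset an \linkS4class{ExperimentDataset}.
#' @param parameters which parameter traces to process.
#' @param qcThresholdPercent OIS contact-gate threshold, percent.
#' @return data.frame with one row per trial x parameter: animal, group,
#'   stage, trial, parameter, integral (fixed window), integralAdaptive,
#'   endS, truncated, preStimSD, qcPassed.
#' @export
responseTable <- function(dataset, parameters = c("apc", "ois", "abp", "hr"),
                          qcThresholdPercent = 7) {
  sch <- dataset@schedule
  protocol <- dataset@protocol
  rows <- vector("list", nrow(sch) * length(parameters))
  n <- 0L
  for (i in seq_len(nrow(sch))) {
    tr <- dataset@traces[[i]]
    # trace-level OIS gate: excess of the OIS-level trace over its pre mean
    preOis <- mean(tr$ois[tr$t < protocol@preS])
    stimSel <- tr$t >= protocol@preS & tr$t < protocol@preS + protocol@stimS
    qcPassed <- (max(tr$ois[stimSel]) - preOis) >= qcThresholdPercent
    for (p in parameters) {
      nt <- normalizeTrace(tr$t, tr[[p]], parameter = toupper(p), protocol)
      ia <- integralAdaptive(nt, protocol)
      n <- n + 1L
      rows[[n]] <- data.frame(
        animal = sch$animal[i], group = sch$group[i],
        stage = as.character(sch$stage[i]), trial = sch$trial[i],
        parameter = toupper(p),
        integral = integralStim(nt, protocol),
        integralAdaptive = ia$integral, endS = ia$endS,
        truncated = ia$truncated, preStimSD = nt@preStimSD,
        qcPassed = qcPassed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(n)])
}

#' Per-animal stage summary of baseline-normalized integrals
#'
#' The value entering the repeated-measures statistics: for one parameter,
#' each animal's mean baseline-normalized adaptive integral over its three
#' trials at each stage.
#'
#' @param responses output of \code{\link{responseTable}}.
#' @param parameter one of "APC", "OIS", "ABP", "HR".
#' @param integralColumn which integral to aggregate
#'   ("integralAdaptive" or "integral").
#' @return data.frame (animal, group, stage, value) with one row per
#'   animal x stage.
#' @export
stageSummary <- function(responses, parameter = "APC",
                         integralColumn = "integralAdaptive") {
  df <- responses[responses$parameter == parameter, , drop = FALSE]
  df$integral <- df[[integralColumn]]
  df <- baselineNormalize(df)
  agg <- stats::aggregate(normIntegral ~ animal + group + stage, data = df,
                          FUN = mean)
  names(agg)[names(agg) == "normIntegral"] <- "value"
  agg[order(agg$animal, agg$stage), ]
}
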