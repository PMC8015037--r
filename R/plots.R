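# Base-graphics views of the main result surfaces.

#' Plot a normalized response trace with trial-phase shading
#'
#' Pre-stimulation, stimulation and relaxation phases are shaded as in the
#' standard trial figures; the 100% pre-stimulation level is marked.
#'
#' @param trace a \linkS4class{NormalizedTrace}.
#' @param protocol a \linkS4class{TrialProtocol}.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotTrace <- function(trace, protocol = TrialProtocol(), ...) {
  t <- traceTimes(trace); v <- traceValues(trace)
  graphics::plot(t, v, type = "n", xlab = "time (s)",
                 ylab = sprintf("%s (%% of pre-stimulation)",
                                trace@parameter), ...)
  usr <- graphics::par("usr")
  t1 <- protocol@preS; t2 <- protocol@preS + protocol@stimS
  graphics::rect(usr[1], usr[3], t1, usr[4], col = "#FFF3C4", border = NA)
  graphics::rect(t1, usr[3], t2, usr[4], col = "#FAD4D4", border = NA)
  graphics::rect(t2, usr[3], usr[2], usr[4], col = "#E6DAF2", border = NA)
  graphics::abline(h = 100, lty = 2, col = "grey40")
  graphics::lines(t, v, lwd = 1.5)
  graphics::box()
  invisible(NULL)
}

#' Pseudo-color image of an APC or OIS map
#'
#' @param map an \linkS4class{APCMap} or \linkS4class{OISMap}.
#' @param main plot title.
#' @param ... passed to \code{image}.
#' @return invisibly, NULL.
#' @export
plotMap <- function(map, main = class(map), ...) {
  V <- mapValues(map)
  V[!mapMask(map)] <- NA
  # image() draws x along rows; transpose and flip for display orientation
  graphics::image(t(V)[, rev(seq_len(nrow(V))), drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main, ...)
  graphics::box()
  invisible(NULL)
}

#' Plot a mean cardiac pulse
#'
#' @param pulse a \linkS4class{MeanPulse}.
#' @param ... passed to \code{plot}.
#' @return invisibly, NULL.
#' @export
plotMeanPulse <- function(pulse, ...) {
  graphics::plot(pulse@phase, 100 * pulse@values, type = "l", lwd = 2,
                 xlab = "cardiac phase", ylab = "AC/DC (%)", ...)
  graphics::abline(h = 0, lty = 3, col = "grey50")
  invisible(NULL)
}

#' Box plots of baseline-normalized integrals by group and stage
#'
#' Median/IQR boxes per stage, one color per group.
#'
#' @param stageValues output of \code{\link{stageSummary}}.
#' @param main plot title.
#' @return invisibly, NULL.
#' @export
plotStageBoxes <- function(stageValues, main = "normalized response") {
  groups <- unique(stageValues$group)
  cols <- grDevices::hcl.colors(max(3, length(groups)), "Dark 3")
  graphics::boxplot(value ~ group + stage, data = stageValues,
                    col = cols[seq_along(groups)], las = 2,
                    xlab = "", ylab = "normalized integral", main = main)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  graphics::legend("topleft", legend = groups, fill = cols, bty = "n")
  invisible(NULL)
}
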