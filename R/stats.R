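# Rank-based statistical design over per-trial response metrics:
# Kolmogorov-Smirnov normality screening, Wilcoxon signed-rank within-trial
# contrasts, Friedman across infusion stages (repeated measures),
# Kruskal-Wallis between groups, all with Bonferroni post-hoc correction.

#' Bonferroni adjustment
#'
#' adjusted p = min(1, m x raw p), with m the declared family size.
#'
#' @param p raw p-values.
#' @param m family size (number of comparisons; defaults to length(p)).
#' @return adjusted p-values (always >= raw).
#' @export
bonferroniAdjust <- function(p, m = length(p)) pmin(1, m * p)

#' Screen a sample for normality (Kolmogorov-Smirnov)
#'
#' KS test against a normal with the sample's mean and SD. The analysis
#' path is nonparametric regardless; the decision is recorded, mirroring
#' the screening that motivated the rank-based tests.
#'
#' @param x numeric sample, n >= 5.
#' @param alpha screening level.
#' @return list: n, statistic, pValue, normalityRejected, degenerate,
#'   decision (always "nonparametric").
#' @export
screenNormality <- function(x, alpha = 0.05) {
  if (length(x) < 5L) stop("normality screening needs n >= 5")
  if (stats::sd(x) < .Machine$double.eps^0.5)
    return(list(n = length(x), statistic = NA_real_, pValue = NA_real_,
                normalityRejected = NA, degenerate = TRUE,
                decision = "nonparametric"))
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(n = length(x), statistic = unname(kt$statistic),
       pValue = kt$p.value, normalityRejected = kt$p.value < alpha,
       degenerate = FALSE, decision = "nonparametric")
}

#' Two-sided Wilcoxon signed-rank test
#'
#' The paired contrast used throughout the analysis plan: exact null
#' distribution for n <= 25 (when free of zeros and ties), normal
#' approximation with continuity correction otherwise. All-zero
#' differences yield a degenerate record with p = 1.
#'
#' @param x numeric vector (differences, or first member of the pairs).
#' @param y optional second member; the test runs on x - y.
#' @return list: statistic (V, sum of positive ranks), pValue, n,
#'   degenerate.
#' @export
wilcoxonSignedRank <- function(x, y = NULL) {
  if (!is.null(y)) x <- x - y
  .signedRank(x)
}

# internal: two-sided Wilcoxon signed-rank on differences, exact for
# n <= 25 (without zeros/ties), normal approximation with continuity and
# tie correction otherwise.
.signedRank <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n == 0L || all(d == 0))
    return(list(statistic = NA_real_, pValue = 1, n = n, degenerate = TRUE))
  useExact <- n <= 25L && all(d != 0) && !any(duplicated(abs(d)))
  wt <- suppressWarnings(stats::wilcox.test(d, exact = useExact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), pValue = wt$p.value, n = n,
       degenerate = FALSE)
}

#' Within-trial pre/post stimulation contrast
#'
#' Compares the normalized parameter at the 10th second of the trial
#' (pre-stimulation phase) against the 30th second (stimulation phase)
#' with a two-sided Wilcoxon signed-rank test. By default each animal
#' contributes the mean of its trials at the chosen stage.
#'
#' @param dataset an \linkS4class{ExperimentDataset}.
#' @param parameter "apc", "ois", "abp" or "hr".
#' @param tPreS,tPostS contrast time points, seconds.
#' @param stage which stage's trials to use ("baseline" by default).
#' @param perAnimal aggregate trials to one value per animal (TRUE) or use
#'   every trial as a pair (FALSE).
#' @return list: test, parameter, statistic, pValue, n, degenerate,
#'   medianPre, medianPost (normalized %).
#' @export
pairedPrePost <- function(dataset, parameter = "apc", tPreS = 10,
                          tPostS = 30, stage = "baseline",
                          perAnimal = TRUE) {
  sch <- dataset@schedule
  protocol <- dataset@protocol
  sel <- which(as.character(sch$stage) == stage)
  if (length(sel) == 0L) stop("no trials at the requested stage")
  pre <- post <- numeric(length(sel)); animal <- sch$animal[sel]
  for (j in seq_along(sel)) {
    tr <- dataset@traces[[sel[j]]]
    nt <- normalizeTrace(tr$t, tr[[parameter]], toupper(parameter), protocol)
    pre[j] <- stats::approx(nt@t, nt@values, xout = tPreS, rule = 2)$y
    post[j] <- stats::approx(nt@t, nt@values, xout = tPostS, rule = 2)$y
  }
  if (perAnimal) {
    pre <- tapply(pre, animal, mean)
    post <- tapply(post, animal, mean)
  }
  res <- .signedRank(post - pre)
  c(list(test = "Wilcoxon signed-rank", parameter = toupper(parameter),
         medianPre = median(pre), medianPost = median(post)), res)
}

#' Friedman test across repeated stages
#'
#' Omnibus Friedman chi-square over the within-animal stage factor
#' (baseline, step 1-3) on per-animal stage values (see
#' \code{\link{stageSummary}}); animals with missing stages are dropped.
#' When the omnibus test rejects, pairwise Wilcoxon signed-rank post-hoc
#' contrasts with Bonferroni correction (family = all stage pairs) are
#' reported.
#'
#' @param stageValues data.frame (animal, stage, value) or an
#'   animals x stages value matrix.
#' @param alpha significance level gating the post-hoc step.
#' @return list: test, statistic (chi-square), df, pValue, n (animals),
#'   dropped, posthoc (data.frame or NULL).
#' @export
repeatedFriedman <- function(stageValues, alpha = 0.05) {
  if (is.data.frame(stageValues)) {
    M <- tapply(stageValues$value, list(stageValues$animal,
                                        stageValues$stage), mean)
  } else M <- as.matrix(stageValues)
  complete <- stats::complete.cases(M)
  dropped <- sum(!complete)
  if (dropped > 0L)
    message(sprintf("dropping %d animal(s) with missing stages", dropped))
  M <- M[complete, , drop = FALSE]
  if (nrow(M) < 2L) stop("need at least two complete animals")
  ft <- suppressWarnings(stats::friedman.test(M))
  if (!is.finite(ft$statistic)) {
    # complete within-block ties (e.g. duplicated identical stages)
    return(list(test = "Friedman", statistic = 0,
                df = unname(ft$parameter), pValue = 1, n = nrow(M),
                dropped = dropped, degenerate = TRUE, posthoc = NULL))
  }
  posthoc <- NULL
  if (is.finite(ft$p.value) && ft$p.value < alpha && ncol(M) >= 2L) {
    prs <- utils::combn(colnames(M), 2L)
    m <- ncol(prs)
    posthoc <- data.frame(
      a = prs[1, ], b = prs[2, ],
      pRaw = vapply(seq_len(m), function(i)
        .signedRank(M[, prs[1, i]] - M[, prs[2, i]])$pValue, numeric(1)))
    posthoc$pAdjusted <- bonferroniAdjust(posthoc$pRaw, m)
  }
  list(test = "Friedman", statistic = unname(ft$statistic),
       df = unname(ft$parameter), pValue = ft$p.value, n = nrow(M),
       dropped = dropped, posthoc = posthoc)
}

#' Kruskal-Wallis test between groups
#'
#' Omnibus Kruskal-Wallis H across treatment groups on per-animal values;
#' when the omnibus test rejects, pairwise two-sided Mann-Whitney contrasts
#' with Bonferroni correction (family = all group pairs) are reported.
#'
#' @param values numeric per-animal values.
#' @param groups group labels, same length.
#' @param alpha significance level gating the post-hoc step.
#' @return list: test, statistic (H), df, pValue, n per group, degenerate,
#'   posthoc (data.frame or NULL).
#' @export
groupsKruskal <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(droplevels(as.factor(groups)))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  ns <- table(groups)
  if (any(ns < 3L)) stop("each group needs n >= 3")
  if (stats::sd(values) < .Machine$double.eps^0.5)
    return(list(test = "Kruskal-Wallis", statistic = 0, df = nlevels(groups) - 1L,
                pValue = 1, n = as.vector(ns), degenerate = TRUE,
                posthoc = NULL))
  kt <- stats::kruskal.test(values, groups)
  posthoc <- NULL
  if (is.finite(kt$p.value) && kt$p.value < alpha) {
    prs <- utils::combn(levels(groups), 2L)
    m <- ncol(prs)
    posthoc <- data.frame(
      a = prs[1, ], b = prs[2, ],
      pRaw = vapply(seq_len(m), function(i)
        suppressWarnings(stats::wilcox.test(
          values[groups == prs[1, i]],
          values[groups == prs[2, i]])$p.value), numeric(1)))
    posthoc$pAdjusted <- bonferroniAdjust(posthoc$pRaw, m)
  }
  list(test = "Kruskal-Wallis", statistic = unname(kt$statistic),
       df = unname(kt$parameter), pValue = kt$p.value, n = as.vector(ns),
       degenerate = FALSE, posthoc = posthoc)
}

#' Full statistical report for one parameter
#'
#' Runs the comparison plan over a response table: descriptive summaries
#' (median with interquartile range per group and stage), per-group
#' Friedman tests across stages, and per-stage Kruskal-Wallis tests across
#' groups, each with Bonferroni post-hoc contrasts where the omnibus test
#' rejects at \code{alpha}.
#'
#' @param responses output of \code{\link{responseTable}}.
#' @param parameter "APC", "OIS", "ABP" or "HR".
#' @param alpha fixed significance level (0.05).
#' @param integralColumn which integral metric enters the tests.
#' @return list of class "statsReport": descriptives, friedman (per group),
#'   kruskal (per stage), alpha, parameter.
#' @export
statsReport <- function(responses, parameter = "APC", alpha = 0.05,
                        integralColumn = "integralAdaptive") {
  sv <- stageSummary(responses, parameter, integralColumn)
  desc <- do.call(rbind, lapply(split(sv, list(sv$group, sv$stage)),
    function(d) {
      if (nrow(d) == 0L) return(NULL)
      q <- stats::quantile(d$value, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(group = d$group[1], stage = d$stage[1], n = nrow(d),
                 q25 = q[1], median = q[2], q75 = q[3])
    }))
  rownames(desc) <- NULL
  fried <- lapply(split(sv, sv$group), repeatedFriedman, alpha = alpha)
  krus <- lapply(split(sv, sv$stage), function(d)
    groupsKruskal(d$value, d$group, alpha = alpha))
  structure(list(parameter = parameter, alpha = alpha, descriptives = desc,
                 friedman = fried, kruskal = krus),
            class = "statsReport")
}

#' @export
print.statsReport <- function(x, ...) {
  cat(sprintf("Statistical report for %s (alpha = %g)\n", x$parameter,
              x$alpha))
  cat("\nMedian [IQR] of baseline-normalized integrals:\n")
  print(x$descriptives, row.names = FALSE, digits = 3)
  cat("\nFriedman across stages (per group):\n")
  for (g in names(x$friedman)) {
    f <- x$friedman[[g]]
    cat(sprintf("  %-12s chi2 = %6.2f, df = %d, p = %.4g, n = %d\n", g,
                f$statistic, f$df, f$pValue, f$n))
  }
  cat("\nKruskal-Wallis across groups (per stage):\n")
  for (s in names(x$kruskal)) {
    k <- x$kruskal[[s]]
    cat(sprintf("  %-10s H = %6.2f, df = %d, p = %.4g\n", s, k$statistic,
                k$df, k$pValue))
  }
  invisible(x)
}
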