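#' @include AllClasses.R postprocess.R
NULL

#' Multiplicity-corrected significance threshold
#'
#' The Bonferroni bound used for histogram-class testing:
#' \code{th = s / nC}, where \code{s} is the significance level and
#' \code{nC} the number of histogram classes tested for the parameter.
#'
#' @param s significance level in (0, 1).
#' @param nC number of histogram classes (>= 1).
#' @return the threshold.
#' @examples
#' significanceThreshold(0.05, 50)   # 0.001
#' @export
significanceThreshold <- function(s, nC) {
  if (nC < 1) stop("nC must be >= 1")
  if (s <= 0 || s >= 1) stop("s must lie in (0, 1)")
  s / nC
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Tests the null hypothesis that two samples come from continuous
#' distributions with equal medians. Exact p-value for small untied
#' samples (total n <= 20), normal approximation with tie correction (and
#' continuity correction) otherwise. Symmetric in its arguments.
#'
#' @param a,b numeric samples (nonempty).
#' @return the two-sided p-value.
#' @examples
#' ranksumTest(c(1, 2, 3), c(10, 11, 12))   # 0.1 (2 / choose(6, 3))
#' @export
ranksumTest <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be nonempty")
  if (length(unique(c(a, b))) == 1) return(1)   # constant data: no evidence
  exact <- (length(a) + length(b)) <= 20 &&
    !any(duplicated(c(a, b)))
  suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = exact, correct = TRUE)$p.value)
}

# Per-subject normalized class frequencies on common edges.
.subjectFrequencies <- function(study, parameter, classWidth) {
  subj <- subjects(study)
  vals <- lapply(subj, function(s) {
    m <- if (methods::is(s$maps, "FitResultMaps"))
      resultMap(s$maps, parameter) else s$maps[[parameter]]
    v <- m[s$roi]
    v[is.finite(v)]
  })
  allv <- unlist(vals)
  lo <- floor(min(allv) / classWidth)
  hi <- floor(max(allv) / classWidth)
  edges <- (lo:(hi + 1)) * classWidth
  freq <- t(vapply(vals, function(v) {
    cnt <- tabulate(floor(v / classWidth) - lo + 1L, nbins = hi - lo + 1L)
    cnt / sum(cnt)
  }, numeric(hi - lo + 1L)))
  list(edges = edges, freq = freq)
}

#' Histogram-class group comparison
#'
#' For one fitted parameter, computes a normalized ROI histogram per
#' subject on common classes, then tests each class's per-subject
#' frequencies between the two groups with a two-sided Wilcoxon rank-sum
#' test. The subject — not the pixel — is the unit of analysis, so pixel
#' counts do not pseudo-replicate. P-values are compared against the
#' Bonferroni bound \code{s / nC} (\code{nC} = number of classes with any
#' observation), or flagged by the Holm step-down rule.
#'
#' @param study a \code{\link{StudySet}} with two groups.
#' @param parameter map name, e.g. \code{"tau1"}.
#' @param classWidth histogram class width (e.g. 5 ps for tau1).
#' @param s significance level.
#' @param mode \code{"bonferroni"} (the plain s/nC bound) or
#'   \code{"holm"} (step-down).
#' @return list of class \code{"ClassComparison"}: \code{edges},
#'   \code{p} (per class, NA for empty classes), \code{significant}
#'   (logical flags), \code{threshold}, \code{nC}, \code{bestClass}
#'   (index of the smallest p), \code{frequencies} (subjects x classes),
#'   \code{groups}.
#' @export
compareGroups <- function(study, parameter, classWidth, s = 0.05,
                          mode = c("bonferroni", "holm")) {
  mode <- match.arg(mode)
  groups <- groupLabels(study)
  glev <- unique(groups)
  if (length(glev) != 2) stop("exactly two groups are required")
  if (any(table(groups) < 2)) stop("each group needs >= 2 subjects")
  sf <- .subjectFrequencies(study, parameter, classWidth)
  observed <- colSums(sf$freq) > 0
  nC <- sum(observed)
  nClasses <- ncol(sf$freq)
  p <- rep(NA_real_, nClasses)
  for (k in which(observed))
    p[k] <- ranksumTest(sf$freq[groups == glev[1], k],
                        sf$freq[groups == glev[2], k])
  th <- significanceThreshold(s, nC)
  sig <- rep(FALSE, nClasses)
  if (mode == "bonferroni") {
    sig[!is.na(p)] <- p[!is.na(p)] < th
  } else {
    idx <- which(!is.na(p))
    ord <- idx[order(p[idx])]
    for (r in seq_along(ord)) {
      if (p[ord[r]] < s / (nC - r + 1)) sig[ord[r]] <- TRUE else break
    }
  }
  best <- if (any(!is.na(p))) which.min(p) else NA_integer_
  structure(list(edges = sf$edges, p = p, significant = sig,
                 threshold = th, nC = nC, bestClass = best,
                 frequencies = sf$freq, groups = groups, mode = mode,
                 parameter = parameter),
            class = "ClassComparison")
}

#' @export
print.ClassComparison <- function(x, ...) {
  cat(sprintf("ClassComparison of '%s': %d classes tested (%s), th = %.4g\n",
              x$parameter, x$nC, x$mode, x$threshold))
  cat(sprintf("  %d significant class(es); best class [%g, %g) with p = %.4g\n",
              sum(x$significant),
              x$edges[x$bestClass], x$edges[x$bestClass + 1],
              x$p[x$bestClass]))
  invisible(x)
}

#' ROC analysis of a candidate classifier
#'
#' Builds the ROC curve of patients vs controls over all threshold
#' candidates (midpoints between sorted unique values, plus the
#' extremes), trying both orientations and keeping the one with the
#' larger area. The AUC is the trapezoidal area (equal to the
#' Mann-Whitney U statistic over n1*n2, ties counted one half); the
#' cut-off maximizes Youden's J = sensitivity + specificity - 1.
#'
#' @param patients,controls numeric values of the classifier per subject.
#' @return list of class \code{"RocResult"}: \code{thresholds},
#'   \code{tpr}, \code{fpr}, \code{auc}, \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{direction}
#'   (\code{">="} means larger values indicate a patient).
#' @examples
#' rocAnalysis(c(5, 6, 7), c(1, 2, 3))$auc   # 1
#' @export
rocAnalysis <- function(patients, controls) {
  if (length(patients) == 0 || length(controls) == 0)
    stop("both groups must be nonempty")
  u <- sort(unique(c(patients, controls)))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  build <- function(dir) {
    pos <- if (dir == ">=") function(v, t) v >= t else function(v, t) v <= t
    tpr <- vapply(thr, function(t) mean(pos(patients, t)), 0)
    fpr <- vapply(thr, function(t) mean(pos(controls, t)), 0)
    ord <- order(fpr, tpr)
    fprO <- c(0, fpr[ord], 1); tprO <- c(0, tpr[ord], 1)
    auc <- sum(diff(fprO) * (tprO[-1] + tprO[-length(tprO)]) / 2)
    list(dir = dir, tpr = tpr, fpr = fpr, auc = auc)
  }
  r1 <- build(">="); r2 <- build("<=")
  r <- if (r2$auc > r1$auc) r2 else r1
  j <- r$tpr - r$fpr
  bi <- which.max(j)
  structure(list(thresholds = thr, tpr = r$tpr, fpr = r$fpr, auc = r$auc,
                 cutoff = thr[bi], sensitivity = r$tpr[bi],
                 specificity = 1 - r$fpr[bi], direction = r$dir),
            class = "RocResult")
}

#' @export
print.RocResult <- function(x, ...) {
  cat(sprintf("RocResult: AUC = %.3f, cut-off %s %.4g (sens %.3f, spec %.3f)\n",
              x$auc, x$direction, x$cutoff, x$sensitivity, x$specificity))
  invisible(x)
}
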