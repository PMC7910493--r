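#' Confusion matrix, accuracy and per-class true-positive rates
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param true,predicted equal-length label vectors (factors or
#'   characters).
#' @param levels class order; defaults to the union of factor levels.
#' @return list with `matrix` (counts), `normalized` (row-normalized
#'   rates), `accuracy` and `tpr` (named per-class true-positive rate,
#'   `NaN` for absent classes).
#' @examples
#' confusionStats(c(0, 0, 1), c(0, 1, 1))$accuracy  # 2/3
#' @export
confusionStats <- function(true, predicted, levels = NULL) {
  if (!length(true)) .stopf("empty input")
  if (length(true) != length(predicted))
    .stopf("label vectors must have equal length")
  if (is.null(levels))
    levels <- union(base::levels(factor(true)), base::levels(factor(predicted)))
  tf <- factor(true, levels = levels)
  pf <- factor(predicted, levels = levels)
  if (any(is.na(tf)) || any(is.na(pf))) .stopf("labels outside class levels")
  M <- table(true = tf, predicted = pf)
  M <- matrix(as.integer(M), nrow(M), ncol(M), dimnames = dimnames(M))
  rs <- rowSums(M)
  list(matrix = M,
       normalized = sweep(M, 1, ifelse(rs == 0, 1, rs), `/`),
       accuracy = sum(diag(M)) / sum(M),
       tpr = stats::setNames(diag(M) / rs, levels))
}

.binaryTruth <- function(labels, positiveClass) {
  y <- as.integer(labels == positiveClass)
  if (sum(y) == 0L || sum(y) == length(y))
    .stopf("AUC undefined: need at least one positive and one negative instance")
  y
}

.rankAUC <- function(y, s) {
  r <- rank(s)             # midranks: ties contribute 1/2
  nPos <- sum(y)
  nNeg <- length(y) - nPos
  (sum(r[y == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' One-vs-rest ROC analysis
#'
#' Sweeps thresholds over the unique scores (ties grouped, so the curve
#' steps diagonally through tied blocks) and computes the trapezoidal
#' AUC, which then equals the Mann-Whitney pair statistic with ties
#' counted one half.
#'
#' @param scores numeric vector of positive-class scores, or a matrix
#'   with one column per class (then `positiveClass` selects a column by
#'   name).
#' @param labels true labels.
#' @param positiveClass the class treated as positive.
#' @return list of class `rocCurve`: `points` (data.frame threshold /
#'   fpr / tpr, starting at (0, 0) and ending at (1, 1)) and `auc`.
#' @examples
#' rocOneVsRest(c(0.8, 0.35, 0.4, 0.1), c(1, 1, 0, 0), 1)$auc  # 0.75
#' @export
rocOneVsRest <- function(scores, labels, positiveClass) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)[, as.character(positiveClass)]
  }
  y <- .binaryTruth(labels, positiveClass)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  nPos <- sum(yy); nNeg <- length(yy) - nPos
  grp <- cumsum(!duplicated(s))
  tpCum <- cumsum(yy); fpCum <- cumsum(1 - yy)
  lastIdx <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(threshold = s[lastIdx],
                    fpr = fpCum[lastIdx] / nNeg,
                    tpr = tpCum[lastIdx] / nPos)
  pts <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), pts)
  structure(list(points = pts, auc = .rankAUC(y, scores),
                 positiveClass = positiveClass),
            class = "rocCurve")
}

#' Youden operating point of a ROC curve
#'
#' Maximizes J = sensitivity + specificity - 1; ties break toward
#' higher specificity, then higher threshold.
#'
#' @param roc result of [rocOneVsRest()].
#' @return list with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youdenPoint <- function(roc) {
  pts <- roc$points
  J <- pts$tpr - pts$fpr
  best <- which(J == max(J))
  if (length(best) > 1L) {
    spec <- 1 - pts$fpr[best]
    best <- best[spec == max(spec)]
    if (length(best) > 1L)
      best <- best[which.max(pts$threshold[best])]
  }
  list(threshold = pts$threshold[best], sensitivity = pts$tpr[best],
       specificity = 1 - pts$fpr[best], youden = J[best])
}

#' One-vs-rest precision-recall analysis
#'
#' Precision and recall per score threshold (ties grouped); the summary
#' area uses the average-precision (step interpolation) convention
#' `AP = sum_i (R_i - R_{i-1}) P_i`, not the optimistic trapezoid.
#' When hard predicted labels are supplied the one-vs-rest F1 score is
#' included.
#'
#' @inheritParams rocOneVsRest
#' @param predictedLabels optional hard labels for the F1 score.
#' @return list of class `prCurve`: `points` (threshold / recall /
#'   precision), `auc` (average precision) and `f1` (or `NA`).
#' @examples
#' prOneVsRest(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0), 1)$auc  # 0.8333
#' @export
prOneVsRest <- function(scores, labels, positiveClass,
                        predictedLabels = NULL) {
  if (is.matrix(scores) || is.data.frame(scores)) {
    scores <- as.matrix(scores)[, as.character(positiveClass)]
  }
  y <- as.integer(labels == positiveClass)
  if (sum(y) == 0L) .stopf("recall undefined: no positive instances")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))
  lastIdx <- which(!duplicated(grp, fromLast = TRUE))
  tpCum <- cumsum(yy); n <- seq_along(yy)
  rec <- tpCum[lastIdx] / sum(yy)
  prec <- tpCum[lastIdx] / n[lastIdx]
  ap <- sum(diff(c(0, rec)) * prec)
  f1 <- NA_real_
  if (!is.null(predictedLabels)) {
    pPos <- predictedLabels == positiveClass
    tp <- sum(pPos & y == 1)
    precision <- if (sum(pPos)) tp / sum(pPos) else 0
    recall <- tp / sum(y)
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
  }
  structure(list(points = data.frame(threshold = s[lastIdx], recall = rec,
                                     precision = prec),
                 auc = ap, f1 = f1, positiveClass = positiveClass),
            class = "prCurve")
}

#' Percentile-bootstrap confidence interval
#'
#' Resamples rows with replacement, recomputes the metric and reports
#' the empirical central quantiles.  Degenerate resamples (metric
#' errors or returns `NA`, e.g. a single-class bootstrap sample) are
#' skipped and counted; more than 50% degenerate is an error.
#'
#' @param metricFn function `(labels, scores) -> scalar`.
#' @param labels,scores the data to resample row-wise (scores may be a
#'   vector or matrix).
#' @param nReps bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list of class `BootstrapCI`: `estimate`, `lower`, `upper`,
#'   `level`, `nReps`, `nDegenerate`.
#' @export
bootstrapCI <- function(metricFn, labels, scores, nReps = 10000,
                        level = 0.95, seed = 1) {
  n <- length(labels)
  est <- tryCatch(metricFn(labels, scores), error = function(e) NA_real_)
  mat <- is.matrix(scores) || is.data.frame(scores)
  if (mat) scores <- as.matrix(scores)
  .withSeed(seed, {
    vals <- rep(NA_real_, nReps)
    for (i in seq_len(nReps)) {
      ix <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(
        metricFn(labels[ix], if (mat) scores[ix, , drop = FALSE]
                 else scores[ix]),
        error = function(e) NA_real_)
      vals[i] <- v
    }
    bad <- sum(is.na(vals))
    if (bad > nReps / 2)
      .stopf("bootstrap unreliable: %d of %d resamples degenerate",
             bad, nReps)
    qs <- stats::quantile(vals, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    structure(list(estimate = est, lower = qs[1], upper = qs[2],
                   level = level, nReps = nReps, nDegenerate = bad),
              class = "BootstrapCI")
  })
}

#' @export
print.BootstrapCI <- function(x, ...) {
  cat(sprintf("%.4f (%.0f%% CI %.4f-%.4f, %d reps%s)\n", x$estimate,
              100 * x$level, x$lower, x$upper, x$nReps,
              if (x$nDegenerate) sprintf(", %d degenerate", x$nDegenerate)
              else ""))
  invisible(x)
}

#' AUC as a bootstrap metric
#'
#' Convenience metric function for [bootstrapCI()]: the rank-based
#' (Mann-Whitney) AUC of a score vector against binary membership of
#' `positiveClass`; `NA` on single-class resamples.
#'
#' @param positiveClass the positive class.
#' @return function `(labels, scores) -> numeric`.
#' @export
aucMetric <- function(positiveClass) {
  function(labels, scores) {
    if (is.matrix(scores)) scores <- scores[, as.character(positiveClass)]
    y <- as.integer(labels == positiveClass)
    if (sum(y) == 0L || sum(y) == length(y)) return(NA_real_)
    .rankAUC(y, scores)
  }
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups.  For small samples
#' (both groups at most 20 and at most 1e5 group assignments) the exact
#' permutation distribution of U is enumerated, with ties handled by
#' midranks and the two-sided p-value counting assignments at least as
#' far from the null mean as observed; larger samples use the normal
#' approximation with tie and continuity corrections.  `U` counts pairs
#' where a group-a value exceeds a group-b value (ties one half).
#'
#' @param a,b numeric vectors, each non-empty.
#' @return list with `U` (for group a) and `p`.
#' @examples
#' mannWhitney(c(1, 3), c(2, 4))  # U = 1, p = 0.6667
#' @export
mannWhitney <- function(a, b) {
  if (!length(a) || !length(b)) .stopf("both groups must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  exact <- na <= 20 && nb <= 20 && choose(na + nb, na) <= 1e5
  if (exact) {
    mu <- na * nb / 2
    combs <- utils::combn(na + nb, na)
    allU <- colSums(matrix(r[combs], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(allU - mu) >= abs(U - mu) - 1e-9)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                              correct = TRUE))
    p <- wt$p.value
  }
  list(U = unname(U), p = min(1, p))
}

#' Per-class group statistics and percent differences
#'
#' Mean and standard deviation of one metric per class, plus the matrix
#' of pairwise percent differences `100 (m_row - m_col) / m_col`,
#' rounded to `digits` (integer percent by default, matching how such
#' contrasts are usually reported).
#'
#' @param table feature table with a `class` column.
#' @param metric feature column name.
#' @param classes classes to include (default: all present).
#' @param sdType `"sample"` (n - 1, default) or `"population"`.
#' @param digits rounding for the percent differences.
#' @return list with `stats` (data.frame class / n / mean / sd) and
#'   `percentDiff` (matrix).
#' @export
groupStats <- function(table, metric, classes = NULL,
                       sdType = c("sample", "population"), digits = 0) {
  sdType <- match.arg(sdType)
  if (!metric %in% names(table)) .stopf("no such metric: %s", metric)
  cls <- as.character(table$class)
  if (is.null(classes)) classes <- unique(cls)
  miss <- setdiff(classes, cls)
  if (length(miss)) .stopf("missing class(es): %s", paste(miss, collapse = ", "))
  st <- lapply(classes, function(cl) {
    x <- table[[metric]][cls == cl]
    if (length(x) < 2L) .stopf("class '%s' has fewer than 2 values", cl)
    s <- stats::sd(x)
    if (sdType == "population") s <- s * sqrt((length(x) - 1) / length(x))
    data.frame(class = cl, n = length(x), mean = mean(x), sd = s)
  })
  st <- do.call(rbind, st)
  pd <- outer(st$mean, st$mean,
              function(m1, m2) round(100 * (m1 - m2) / m2, digits))
  dimnames(pd) <- list(st$class, st$class)
  list(stats = st, percentDiff = pd)
}

#' Percent difference between two means
#'
#' `100 (m1 - m2) / m2`, rounded.
#'
#' @param m1,m2 means to compare.
#' @param digits rounding digits.
#' @return numeric.
#' @examples
#' percentDifference(0.43, 0.52)  # -17
#' @export
percentDifference <- function(m1, m2, digits = 0) {
  round(100 * (m1 - m2) / m2, digits)
}

#' Full one-vs-rest evaluation report
#'
#' Confusion matrix, per-class ROC and PR curves, Youden operating
#' points, F1 scores and (optionally) percentile-bootstrap AUC
#' confidence intervals for a multi-class probabilistic prediction.
#'
#' @param true true labels.
#' @param probabilities matrix of class probabilities (columns named by
#'   class).
#' @param predictedLabels hard labels; default argmax of
#'   `probabilities`.
#' @param nBoot bootstrap replicates for the AUC CIs (0 disables).
#' @param level CI level.
#' @param seed integer seed for the bootstrap.
#' @return list of class `EvalReport` with `confusion`, `perClass`
#'   (each: roc, pr, youden, aucCI) and `classes`.
#' @export
evalReport <- function(true, probabilities, predictedLabels = NULL,
                       nBoot = 10000, level = 0.95, seed = 1) {
  probabilities <- as.matrix(probabilities)
  classes <- colnames(probabilities)
  if (is.null(classes)) .stopf("probability columns must be named by class")
  if (is.null(predictedLabels))
    predictedLabels <- classes[max.col(probabilities, ties.method = "first")]
  conf <- confusionStats(true, predictedLabels, levels = classes)
  perClass <- lapply(classes, function(cl) {
    # a class can be absent from a (small) test set: its one-vs-rest
    # curves are then undefined and reported as NULL
    roc <- tryCatch(rocOneVsRest(probabilities, true, cl),
                    error = function(e) NULL)
    pr <- tryCatch(prOneVsRest(probabilities, true, cl, predictedLabels),
                   error = function(e) NULL)
    ci <- if (!is.null(roc) && nBoot > 0)
      bootstrapCI(aucMetric(cl), true, probabilities, nReps = nBoot,
                  level = level, seed = seed) else NULL
    list(roc = roc, pr = pr,
         youden = if (!is.null(roc)) youdenPoint(roc) else NULL,
         aucCI = ci)
  })
  names(perClass) <- classes
  structure(list(confusion = conf, perClass = perClass, classes = classes),
            class = "EvalReport")
}

#' @export
print.EvalReport <- function(x, ...) {
  cat(sprintf("EvalReport: %d classes, accuracy %.3f\n",
              length(x$classes), x$confusion$accuracy))
  for (cl in x$classes) {
    pc <- x$perClass[[cl]]
    if (is.null(pc$roc)) {
      cat(sprintf("  %-18s (absent from the evaluated set)\n", cl))
      next
    }
    cat(sprintf("  %-18s AUC %.3f  PR-AUC %.3f  F1 %.3f  sens %.3f  spec %.3f\n",
                cl, pc$roc$auc, pc$pr$auc, pc$pr$f1,
                pc$youden$sensitivity, pc$youden$specificity))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Summary as JSON plus per-class ROC and PR curve tables as TSV.
#'
#' @param report an [evalReport()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- list(
    accuracy = report$confusion$accuracy,
    tpr = as.list(report$confusion$tpr),
    confusion = report$confusion$matrix,
    perClass = lapply(report$perClass, function(pc) {
      if (is.null(pc$roc)) return(list(auc = NA))
      out <- list(auc = pc$roc$auc, prAuc = pc$pr$auc, f1 = pc$pr$f1,
                  sensitivity = pc$youden$sensitivity,
                  specificity = pc$youden$specificity)
      if (!is.null(pc$aucCI))
        out$aucCI <- c(pc$aucCI$lower, pc$aucCI$upper)
      out
    }))
  path <- file.path(dir, "eval_report.json")
  jsonlite::write_json(summ, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  for (cl in report$classes) {
    if (is.null(report$perClass[[cl]]$roc)) next
    utils::write.table(report$perClass[[cl]]$roc$points,
                       file.path(dir, sprintf("roc_%s.tsv", cl)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$perClass[[cl]]$pr$points,
                       file.path(dir, sprintf("pr_%s.tsv", cl)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Plot ROC and PR panels
#'
#' One row of ROC curves and one of PR curves, one panel per class
#' (base graphics).
#'
#' @param report an [evalReport()] result.
#' @param file optional PNG path; default plots to the active device.
#' @return invisibly, `NULL`.
#' @export
plotEvalReport <- function(report, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 300 * length(report$classes), height = 600)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, length(report$classes)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  for (cl in report$classes) {
    if (is.null(report$perClass[[cl]]$roc)) { plot.new(); next }
    p <- report$perClass[[cl]]$roc$points
    plot(p$fpr, p$tpr, type = "l", xlim = 0:1, ylim = 0:1,
         xlab = "FPR", ylab = "TPR",
         main = sprintf("%s AUC %.3f", cl, report$perClass[[cl]]$roc$auc))
    graphics::abline(0, 1, lty = 3)
  }
  for (cl in report$classes) {
    if (is.null(report$perClass[[cl]]$pr)) { plot.new(); next }
    p <- report$perClass[[cl]]$pr$points
    plot(p$recall, p$precision, type = "s", xlim = 0:1, ylim = 0:1,
         xlab = "Recall", ylab = "Precision",
         main = sprintf("%s AP %.3f", cl, report$perClass[[cl]]$pr$auc))
  }
  invisible(NULL)
}

#' Ages of the studied patient cohort
#'
#' Demographics of the nine-patient autopsy cohort the method was
#' developed on: age at initial diagnosis and at autopsy (years) per
#' patient.  Useful as a worked example for [groupStats()]-style
#' summaries with the population-SD convention.
#'
#' @return data.frame with `patient`, `ageDiagnosis`, `ageAutopsy`.
#' @examples
#' d <- patientDemographics()
#' round(mean(d$ageDiagnosis), 1)  # 10.8
#' @export
patientDemographics <- function() {
  data.frame(
    patient = paste0("P", 1:9),
    ageDiagnosis = c(9, 11, 11, 7, 10, 13, 4, 17, 15),
    ageAutopsy = c(9, 14, 12, 16, 10, 14, 7, 18, 18))
}
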