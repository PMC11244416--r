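#' Confusion counts for binary predictions
#'
#' @param yTrue,yPred equal-length binary vectors (1 = positive class).
#' @return named integer vector with TP, FP, TN, FN.
#' @export
confusionCounts <- function(yTrue, yPred) {
  if (length(yTrue) == 0L) stop("empty input")
  stopifnot(length(yTrue) == length(yPred),
            all(yTrue %in% c(0, 1)), all(yPred %in% c(0, 1)))
  c(TP = sum(yTrue == 1 & yPred == 1),
    FP = sum(yTrue == 0 & yPred == 1),
    TN = sum(yTrue == 0 & yPred == 0),
    FN = sum(yTrue == 1 & yPred == 0))
}

safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " is undefined (zero denominator)", call. = FALSE)
    return(NA_real_)
  }
  num / den
}

#' Imbalance-aware classification metrics from confusion counts
#'
#' TPR = TP/(TP+FN), TNR = TN/(FP+TN), FPR = FP/(FP+TN),
#' precision = TP/(TP+FP), BA = (TPR+TNR)/2,
#' F1 = 2 precision recall / (precision + recall). A ratio whose
#' denominator is zero is reported as \code{NA} (undefined) with a
#' warning — never silently 0, which would distort BA on degenerate
#' folds.
#'
#' @param counts named vector with TP, FP, TN, FN.
#' @return named numeric vector of metrics (without AUC).
#' @export
classificationMetrics <- function(counts) {
  counts <- counts[c("TP", "FP", "TN", "FN")]
  stopifnot(!any(is.na(counts)), all(counts >= 0))
  if (sum(counts) == 0) stop("all confusion counts are zero")
  TP <- counts[["TP"]]; FP <- counts[["FP"]]
  TN <- counts[["TN"]]; FN <- counts[["FN"]]
  TPR <- safeRatio(TP, TP + FN, "TPR")
  TNR <- safeRatio(TN, FP + TN, "TNR")
  FPR <- if (is.na(TNR)) NA_real_ else 1 - TNR
  precision <- safeRatio(TP, TP + FP, "precision")
  BA <- if (is.na(TPR) || is.na(TNR)) NA_real_ else (TPR + TNR) / 2
  F1 <- if (is.na(precision) || is.na(TPR) || precision + TPR == 0) {
    if (!is.na(precision) && !is.na(TPR)) {
      warning("F1 is undefined (precision + recall = 0)", call. = FALSE)
    }
    NA_real_
  } else {
    2 * precision * TPR / (precision + TPR)
  }
  c(TPR = TPR, TNR = TNR, FPR = FPR, precision = precision, recall = TPR,
    BA = BA, F1 = F1)
}

#' Rank-based AUC (Mann-Whitney with midrank ties)
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted half — the Mann-Whitney U estimator of
#' the area under the ROC curve. Invariant under strictly increasing
#' transformations of the scores.
#'
#' @param scores numeric scores.
#' @param labels binary labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
rocAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  nPos <- sum(labels == 1); nNeg <- sum(labels == 0)
  if (nPos == 0L || nNeg == 0L) stop("AUC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Build an EvalReport from scores and labels
#'
#' @param yTrue binary ground truth.
#' @param scores predicted scores in (0, 1).
#' @param threshold decision threshold (score at threshold is positive).
#' @param fold optional fold identifier recorded in \code{perFold}.
#' @return an [EvalReport-class].
#' @export
evalReport <- function(yTrue, scores, threshold = 0.5, fold = 1L) {
  yPred <- as.integer(scores >= threshold)
  counts <- confusionCounts(yTrue, yPred)
  met <- classificationMetrics(counts)
  auc <- rocAUC(scores, yTrue)
  metrics <- c(met, AUC = auc)
  pf <- data.frame(fold = fold, TP = counts[["TP"]], FP = counts[["FP"]],
                   TN = counts[["TN"]], FN = counts[["FN"]],
                   t(metrics))
  new("EvalReport", TP = as.integer(counts[["TP"]]), FP = as.integer(counts[["FP"]]),
      TN = as.integer(counts[["TN"]]), FN = as.integer(counts[["FN"]]),
      metrics = metrics, perFold = pf)
}

#' Combine per-fold reports into a cross-validation summary
#'
#' Counts are pooled; metric slots hold the across-fold means, and the
#' \code{perFold} table keeps each fold's row (mean and sd are shown by
#' \code{show}).
#'
#' @param reports list of [EvalReport-class] objects.
#' @return an [EvalReport-class].
#' @export
combineReports <- function(reports) {
  stopifnot(length(reports) >= 1L)
  pf <- do.call(rbind, lapply(seq_along(reports), function(i) {
    x <- reports[[i]]@perFold; x$fold <- i; x
  }))
  mcols <- c("TPR", "TNR", "FPR", "precision", "recall", "BA", "F1", "AUC")
  met <- colMeans(pf[mcols], na.rm = TRUE)
  new("EvalReport",
      TP = sum(pf$TP), FP = sum(pf$FP), TN = sum(pf$TN), FN = sum(pf$FN),
      metrics = met, perFold = pf)
}

#' @export
setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: TP %d, FP %d, TN %d, FN %d (n = %d)\n",
              object@TP, object@FP, object@TN, object@FN,
              object@TP + object@FP + object@TN + object@FN))
  m <- object@metrics
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  cat(sprintf("  BA %s, F1 %s, TPR %s, TNR %s, FPR %s, AUC %s\n",
              fmt(m[["BA"]]), fmt(m[["F1"]]), fmt(m[["TPR"]]),
              fmt(m[["TNR"]]), fmt(m[["FPR"]]), fmt(m[["AUC"]])))
  if (nrow(object@perFold) > 1L) {
    sds <- apply(object@perFold[c("BA", "F1", "AUC")], 2, stats::sd)
    cat(sprintf("  %d folds; BA %s±%.4f, F1 %s±%.4f, AUC %s±%.4f\n",
                nrow(object@perFold), fmt(m[["BA"]]), sds[1],
                fmt(m[["F1"]]), sds[2], fmt(m[["AUC"]]), sds[3]))
  }
})

#' Write an EvalReport to JSON or CSV
#'
#' JSON holds the pooled counts, summary metrics, and the per-fold rows;
#' CSV holds the per-fold rows followed by mean and sd summary rows
#' (mean ± sd style).
#'
#' @param report an [EvalReport-class].
#' @param path output path; format chosen by extension (.json or .csv).
#' @export
writeReport <- function(report, path) {
  pf <- report@perFold
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(counts = list(TP = report@TP, FP = report@FP,
                              TN = report@TN, FN = report@FN),
                metrics = as.list(report@metrics),
                perFold = pf)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    mcols <- setdiff(names(pf), "fold")
    mean_row <- c(fold = "mean", as.list(colMeans(pf[mcols], na.rm = TRUE)))
    sd_row <- c(fold = "sd", as.list(apply(pf[mcols], 2, stats::sd, na.rm = TRUE)))
    out <- rbind(data.frame(lapply(pf, as.character), check.names = FALSE),
                 data.frame(lapply(mean_row, as.character), check.names = FALSE),
                 data.frame(lapply(sd_row, as.character), check.names = FALSE))
    utils::write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

#' Pointwise t-test significance windows between two conditions
#'
#' Paired two-sided t-test at every time point between per-subject
#' average ERPs of two conditions, returning maximal runs of consecutive
#' points with p below \code{alpha} as half-open sample windows
#' (0-based \code{start}, exclusive \code{end}). No multiple-comparison
#' correction is applied (the conventional shaded-window procedure).
#' Time points with zero within-pair variance have an undefined p-value
#' and are treated as non-significant, with a warning.
#'
#' @param condA,condB matrices \code{[nSubjects, T]} of per-subject
#'   average ERPs, rows paired by subject.
#' @param alpha significance level.
#' @param minRun minimum run length (samples) for a window to be kept.
#' @return data.frame with columns \code{start}, \code{end} (samples).
#' @export
significantWindows <- function(condA, condB, alpha = 0.05, minRun = 1L) {
  stopifnot(is.matrix(condA), all(dim(condA) == dim(condB)), nrow(condA) >= 2L,
            alpha > 0, alpha < 1)
  d <- condA - condB
  n <- nrow(d)
  m <- colMeans(d)
  s <- apply(d, 2L, stats::sd)
  degenerate <- s == 0
  if (any(degenerate))
    warning(sum(degenerate), " time point(s) with zero within-pair variance; ",
            "treated as non-significant", call. = FALSE)
  tstat <- ifelse(degenerate, 0, m / (s / sqrt(n)))
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  sig <- !degenerate & p < alpha
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}
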