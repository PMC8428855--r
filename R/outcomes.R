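#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all score thresholds (tied scores grouped
#' into a single step) and the trapezoidal AUC. The direction is always
#' explicit: with \code{"greater"}, higher scores predict the positive class
#' (e.g. higher end pipette resistance predicting a good morphology outcome).
#' The trapezoidal AUC equals the concordant-pair probability with ties
#' counted half (the Mann-Whitney identity).
#'
#' @param scores numeric.
#' @param labels logical (or 0/1): TRUE marks the positive class.
#' @param direction "greater" or "less".
#' @return A [ROCResult-class].
#' @examples
#' rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))@auc  # 1
#' @export
rocAuc <- function(scores, labels, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels)) stop("scores and labels must not be NA")
  if (!any(labels) || all(labels)) {
    stop("both classes must be present")
  }
  s <- if (direction == "greater") scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  nPos <- sum(labels); nNeg <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(s[labels] >= t) / nPos, numeric(1))
  fpr <- vapply(thr, function(t) sum(s[!labels] >= t) / nNeg, numeric(1))
  fpr <- c(0, fpr); tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  new("ROCResult", thresholds = c(Inf, thr), fpr = fpr, tpr = tpr,
      auc = auc, direction = direction)
}

#' Operating-point summary at a score cutoff
#'
#' With direction \code{"greater"} (higher score predicts a good outcome),
#' cells scoring strictly below the cutoff are excluded. Returns the fraction
#' of failed-outcome cells excluded and the fraction of good-outcome cells
#' lost at that cutoff — the trade-off quoted for an end-pipette-resistance
#' cutoff (excluding a sizable share of morphology failures at a small cost
#' in good morphologies).
#'
#' @param scores numeric.
#' @param labels logical: TRUE = good outcome.
#' @param cutoff numeric; may lie outside the score range.
#' @param direction "greater" or "less".
#' @return named numeric: \code{failedExcluded}, \code{goodLost}.
#' @export
operatingPoint <- function(scores, labels, cutoff,
                           direction = c("greater", "less")) {
  direction <- match.arg(direction)
  labels <- as.logical(labels)
  s <- if (direction == "greater") scores else -scores
  cut <- if (direction == "greater") cutoff else -cutoff
  excluded <- s < cut
  c(failedExcluded = mean(excluded[!labels]),
    goodLost = mean(excluded[labels]))
}

#' Two-group comparison of a metric (convenience)
#'
#' Thin wrapper over \code{stats::t.test} (Welch by default) for group-level
#' comparisons such as NMS by nucleus outcome.
#'
#' @param x numeric metric.
#' @param group logical or two-level factor.
#' @param ... passed to [stats::t.test()].
#' @return an \code{htest} object.
#' @export
compareGroups <- function(x, group, ...) {
  stats::t.test(x ~ factor(group), ...)
}
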