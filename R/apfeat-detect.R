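#' Offline AP detection parameters
#'
#' The detector names three refinement filters; their defaults follow the
#' conventions of the standard intracellular feature-extraction toolchain and
#' are all configurable: a detected event must rise at least \code{minHeight}
#' mV from threshold to peak, do so within \code{maxInterval} ms, and reach
#' an absolute peak of at least \code{minPeak} mV.
#'
#' @param thresholdDvdt detection threshold on the smoothed derivative,
#'   mV/ms (strict).
#' @param smoothSamples centered boxcar width (samples).
#' @param minHeight minimal threshold-to-peak voltage, mV.
#' @param maxInterval maximal threshold-to-peak time, ms.
#' @param minPeak minimal absolute peak voltage, mV.
#' @param thrFrac fraction of the average maximal dV/dt defining the refined
#'   threshold (the 5% rule).
#' @return list of parameters.
#' @export
apParams <- function(thresholdDvdt = 20, smoothSamples = 5L, minHeight = 2,
                     maxInterval = 5, minPeak = -30, thrFrac = 0.05) {
  list(thresholdDvdt = thresholdDvdt, smoothSamples = as.integer(smoothSamples),
       minHeight = minHeight, maxInterval = maxInterval, minPeak = minPeak,
       thrFrac = thrFrac)
}

#' Centered boxcar-smoothed derivative of a voltage trace
#'
#' Central-difference derivative in mV/ms, smoothed with a centered boxcar.
#' Shared by the offline detector and the threshold-refinement rule.
#'
#' @param voltage mV.
#' @param dt s.
#' @param smoothSamples boxcar width.
#' @return numeric, same length as voltage.
#' @export
smoothedDvdt <- function(voltage, dt, smoothSamples = 5L) {
  n <- length(voltage)
  d <- numeric(n)
  if (n >= 3L) {
    d[2:(n - 1)] <- (voltage[3:n] - voltage[1:(n - 2)]) / (2 * dt * 1000)
  }
  d[1] <- d[2]
  d[n] <- d[n - 1]
  s <- as.numeric(stats::filter(d, rep(1 / smoothSamples, smoothSamples),
                                sides = 2))
  s[is.na(s)] <- d[is.na(s)]
  s
}

#' Refine an AP threshold by the average-maximal-dV/dt rule
#'
#' The threshold is moved to the last sample before the peak at which the
#' smoothed dV/dt rises through \code{thrFrac} (default 5%) of the average
#' maximal dV/dt across all APs of the sweep. If the derivative never crosses
#' that level before the peak, the detection index is returned unchanged.
#' Because the rule is a ratio, it is invariant to scaling the whole trace.
#'
#' @param voltage mV.
#' @param dt s.
#' @param detectIndex sample at which detection triggered.
#' @param peakIndex sample of the AP peak.
#' @param avgMaxDvdt the per-sweep average maximal dV/dt, mV/ms.
#' @param params from [apParams()].
#' @return integer threshold sample index.
#' @export
refineThreshold <- function(voltage, dt, detectIndex, peakIndex, avgMaxDvdt,
                            params = apParams()) {
  s <- smoothedDvdt(voltage, dt, params$smoothSamples)
  level <- params$thrFrac * avgMaxDvdt
  i <- peakIndex
  while (i > 1L && !(s[i - 1L] < level && s[i] >= level)) i <- i - 1L
  if (i == 1L) detectIndex else i
}

#' Detect and characterize action potentials in a sweep
#'
#' Detection: upward crossings of the centered boxcar-smoothed dV/dt above
#' \code{thresholdDvdt}. Each candidate's peak is the voltage maximum within
#' \code{maxInterval} ms; candidates sharing a peak are merged. The threshold
#' sample is then refined by the 5% average-maximal-dV/dt rule
#' ([refineThreshold()]), and events are kept only if they pass the
#' refinement filters (threshold-to-peak height, time and absolute peak; see
#' [apParams()]). Shape features are attached via [apShapeFeatures()].
#'
#' @param voltage mV, uniformly sampled.
#' @param dt s.
#' @param params from [apParams()].
#' @return data.frame with one row per AP: detect/threshold/peak/trough
#'   sample indices, threshold and peak voltages, width at half height (ms),
#'   upstroke and downstroke (mV/ms), and their ratio. Zero rows when no AP
#'   is found.
#' @export
detectAPs <- function(voltage, dt, params = apParams()) {
  n <- length(voltage)
  empty <- data.frame(
    detectIndex = integer(), thresholdIndex = integer(),
    peakIndex = integer(), troughIndex = integer(),
    thresholdV = numeric(), peakV = numeric(),
    widthHalfHeight = numeric(), upstroke = numeric(),
    downstroke = numeric(), upstrokeDownstrokeRatio = numeric())
  if (n < 3L) return(empty)
  s <- smoothedDvdt(voltage, dt, params$smoothSamples)
  above <- s > params$thresholdDvdt
  cross <- which(above & !c(FALSE, above[-n]))
  if (!length(cross)) return(empty)

  win <- max(1L, round(params$maxInterval / 1000 / dt))
  peaks <- vapply(cross, function(i) {
    j <- min(n, i + win)
    i - 1L + which.max(voltage[i:j])
  }, integer(1))
  keep <- !duplicated(peaks)
  cross <- cross[keep]
  peaks <- peaks[keep]

  # sweep-wide average maximal dV/dt over the detected APs
  maxDvdt <- mapply(function(i, p) max(s[i:p]), cross, peaks)
  avgMax <- mean(maxDvdt)

  thr <- mapply(function(i, p) {
    refineThreshold(voltage, dt, i, p, avgMax, params)
  }, cross, peaks)

  # refinement filters
  height <- voltage[peaks] - voltage[thr]
  dtToPeak <- (peaks - thr) * dt * 1000
  ok <- height >= params$minHeight & dtToPeak <= params$maxInterval &
    voltage[peaks] >= params$minPeak
  cross <- cross[ok]; peaks <- peaks[ok]; thr <- thr[ok]
  if (!length(cross)) return(empty)

  # troughs: minimum between each peak and the next AP's threshold (or a
  # maxInterval-scaled window / trace end)
  trough <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    hi <- if (k < length(peaks)) thr[k + 1L] else
      min(n, peaks[k] + 4L * win)
    seg <- peaks[k]:hi
    trough[k] <- seg[which.min(voltage[seg])]
  }

  ev <- data.frame(
    detectIndex = as.integer(cross), thresholdIndex = as.integer(thr),
    peakIndex = as.integer(peaks), troughIndex = as.integer(trough),
    thresholdV = voltage[thr], peakV = voltage[peaks],
    widthHalfHeight = NA_real_, upstroke = NA_real_, downstroke = NA_real_,
    upstrokeDownstrokeRatio = NA_real_)
  for (k in seq_len(nrow(ev))) {
    f <- apShapeFeatures(ev[k, ], voltage, dt, params)
    ev$widthHalfHeight[k] <- f["widthHalfHeight"]
    ev$upstroke[k] <- f["upstroke"]
    ev$downstroke[k] <- f["downstroke"]
    ev$upstrokeDownstrokeRatio[k] <- f["upstrokeDownstrokeRatio"]
  }
  ev
}

#' Shape features of one detected AP
#'
#' Width at half height is measured at half of (peakV - thresholdV), with
#' linear interpolation at the two crossings; upstroke is the maximum
#' smoothed dV/dt between threshold and peak, downstroke the minimum between
#' peak and trough, and the ratio their absolute quotient. A flat segment
#' that prevents a half-height crossing yields an NA width.
#'
#' @param event one row of the [detectAPs()] table (threshold, peak and
#'   trough indices populated).
#' @param voltage mV.
#' @param dt s.
#' @param params from [apParams()].
#' @return named numeric: widthHalfHeight (ms), upstroke, downstroke
#'   (mV/ms), upstrokeDownstrokeRatio.
#' @export
apShapeFeatures <- function(event, voltage, dt, params = apParams()) {
  s <- smoothedDvdt(voltage, dt, params$smoothSamples)
  thr <- event$thresholdIndex; pk <- event$peakIndex; tr <- event$troughIndex
  half <- (voltage[thr] + voltage[pk]) / 2
  crossTime <- function(idx, rising) {
    v <- voltage[idx]
    hit <- if (rising) which(v[-1] >= half & v[-length(v)] < half) else
      which(v[-1] <= half & v[-length(v)] > half)
    if (!length(hit)) return(NA_real_)
    i <- hit[1]
    frac <- (half - v[i]) / (v[i + 1] - v[i])
    (idx[i] - 1 + frac) * dt * 1000
  }
  tUp <- if (pk > thr) crossTime(thr:pk, TRUE) else NA_real_
  tDn <- if (tr > pk) crossTime(pk:tr, FALSE) else NA_real_
  width <- tDn - tUp
  upstroke <- max(s[thr:pk])
  downstroke <- min(s[pk:tr])
  ratio <- abs(upstroke) / abs(downstroke)
  c(widthHalfHeight = width, upstroke = upstroke, downstroke = downstroke,
    upstrokeDownstrokeRatio = ratio)
}
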