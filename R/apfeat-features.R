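#' Feature-vector construction configuration
#'
#' @param stepOffsets suprathreshold amplitudes relative to rheobase, pA.
#' @param binMs bin width for the firing-rate features, ms.
#' @param subAmps subthreshold step amplitudes used, pA.
#' @param subBinMs bin width for subthreshold responses, ms.
#' @param apWindowMs window around the first-AP threshold, ms (start, end).
#' @param apPoints resampled length of the first-AP waveform.
#' @param isiPoints resampled length of each ISI segment.
#' @param hypPoints resampled length of the hyperpolarizing-step response.
#' @param params AP-detection parameters ([apParams()]).
#' @return list of settings for [buildFeatureMatrix()].
#' @export
featureConfig <- function(stepOffsets = c(0, 40, 80), binMs = 20,
                          subAmps = c(-10, -50, -90), subBinMs = 10,
                          apWindowMs = c(-1, 4), apPoints = 250L,
                          isiPoints = 100L, hypPoints = 100L,
                          params = apParams()) {
  list(stepOffsets = stepOffsets, binMs = binMs, subAmps = subAmps,
       subBinMs = subBinMs, apWindowMs = apWindowMs,
       apPoints = as.integer(apPoints), isiPoints = as.integer(isiPoints),
       hypPoints = as.integer(hypPoints), params = params)
}

resampleVec <- function(x, nOut) {
  if (length(x) == 1L) return(rep(as.numeric(x), nOut))
  stats::approx(seq_along(x), x, n = nOut)$y
}

# AP threshold times (s) within a step, from the offline detector.
stepSpikeTimes <- function(sweep, params) {
  ev <- detectAPs(sweep@voltage, sweep@dt, params)
  on <- sweep@epochs$onset[1]; off <- sweep@epochs$offset[1]
  tms <- sweepTimes(sweep)
  t <- tms[ev$thresholdIndex]
  list(events = ev[t >= on & t < off, , drop = FALSE],
       times = t[t >= on & t < off] - on)
}

# Binned instantaneous firing rate, normalized to the step maximum.
binnedRate <- function(spikeTimes, stepDur, binS) {
  nBins <- round(stepDur / binS)
  rate <- numeric(nBins)
  st <- spikeTimes
  if (length(st) >= 2L) {
    f <- 1 / diff(st)
    b <- pmin(nBins, floor(st[-1] / binS) + 1L)
    for (k in seq_along(f)) rate[b[k]] <- max(rate[b[k]], f[k])
  } else if (length(st) == 1L) {
    rate[pmin(nBins, floor(st / binS) + 1L)] <- 1
  }
  mx <- max(rate)
  if (mx > 0) rate <- rate / mx
  rate
}

# Binned mean voltage over a step.
binnedVoltage <- function(sweep, binS) {
  on <- sweep@epochs$onset[1]; off <- sweep@epochs$offset[1]
  nBins <- round((off - on) / binS)
  vapply(seq_len(nBins), function(k) {
    idx <- sampleWindow(sweep, on + (k - 1) * binS, on + k * binS)
    mean(sweep@voltage[idx])
  }, numeric(1))
}

# Fill a missing amplitude from the nearest available neighbors (mean of the
# two flanking amplitudes; one-sided copy at the grid edge).
interpolateAmp <- function(target, avail, vectors) {
  lower <- avail[avail < target]
  upper <- avail[avail > target]
  if (length(lower) && length(upper)) {
    (vectors[[as.character(max(lower))]] +
       vectors[[as.character(min(upper))]]) / 2
  } else if (length(lower)) {
    vectors[[as.character(max(lower))]]
  } else if (length(upper)) {
    vectors[[as.character(min(upper))]]
  } else {
    NULL
  }
}

#' Build the six-category electrophysiology feature matrix
#'
#' For each cell (a list of single-epoch long-square sweeps over an amplitude
#' grid) this assembles: (a) the first-AP waveform of the lowest-amplitude
#' suprathreshold step, resampled to a fixed window around threshold; (b) its
#' smoothed derivative; (c) trough-to-next-threshold interspike segments,
#' duration-normalized and averaged; (d) binned instantaneous firing rate at
#' rheobase, +40 and +80 pA, normalized to the per-step maximum, with missing
#' amplitudes filled by averaging the flanking available sweeps; (e) binned
#' subthreshold voltage responses at -10/-50/-90 pA (same interpolation
#' rule); (f) the largest hyperpolarizing step min/baseline-normalized to
#' [0, 1]. Cells with no suprathreshold or no subthreshold sweeps are dropped
#' and reported in the \code{dropped} slot.
#'
#' @param cells named list; each element a list of [VoltageSweep-class]
#'   objects, each carrying exactly one \code{long_square} epoch.
#' @param config from [featureConfig()].
#' @return A [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(cells, config = featureConfig()) {
  if (is.null(names(cells))) names(cells) <- sprintf("cell%03d",
                                                     seq_along(cells))
  rows <- list()
  dropped <- character()
  catLabels <- NULL
  for (id in names(cells)) {
    row <- cellFeatureRow(cells[[id]], config)
    if (is.null(row)) {
      dropped <- c(dropped, id)
      next
    }
    if (is.null(catLabels)) catLabels <- attr(row, "category")
    rows[[id]] <- as.numeric(row)
  }
  if (!length(rows)) {
    return(new("FeatureMatrix",
               values = matrix(0, 0, 0), category = character(),
               dropped = dropped))
  }
  values <- do.call(rbind, rows)
  colnames(values) <- sprintf("%s%03d", catLabels,
                              stats::ave(seq_along(catLabels), catLabels,
                                         FUN = seq_along))
  new("FeatureMatrix", values = values, category = catLabels,
      dropped = dropped)
}

cellFeatureRow <- function(sweeps, config) {
  amps <- vapply(sweeps, function(s) s@epochs$amplitude[1], numeric(1))
  spk <- lapply(sweeps, stepSpikeTimes, params = config$params)
  nSpikes <- vapply(spk, function(x) length(x$times), integer(1))

  supra <- which(amps > 0 & nSpikes >= 1L)
  if (!length(supra)) return(NULL)
  rheoIdx <- supra[which.min(amps[supra])]
  rheo <- amps[rheoIdx]
  stepDur <- sweeps[[rheoIdx]]@epochs$offset[1] -
    sweeps[[rheoIdx]]@epochs$onset[1]

  # (a, b) first AP of the lowest suprathreshold step
  sw <- sweeps[[rheoIdx]]
  ev1 <- spk[[rheoIdx]]$events[1, ]
  i0 <- ev1$thresholdIndex + round(config$apWindowMs[1] / 1000 / sw@dt)
  i1 <- ev1$thresholdIndex + round(config$apWindowMs[2] / 1000 / sw@dt)
  i0 <- max(1L, i0); i1 <- min(length(sw@voltage), i1)
  featA <- resampleVec(sw@voltage[i0:i1], config$apPoints)
  featB <- resampleVec(smoothedDvdt(sw@voltage, sw@dt,
                                    config$params$smoothSamples)[i0:i1],
                       config$apPoints)

  # (c) duration-normalized ISI segments, averaged
  isiSegs <- list()
  for (j in supra[amps[supra] <= rheo + max(config$stepOffsets)]) {
    ev <- spk[[j]]$events
    if (nrow(ev) >= 2L) {
      for (k in seq_len(nrow(ev) - 1L)) {
        seg <- sweeps[[j]]@voltage[ev$troughIndex[k]:ev$thresholdIndex[k + 1L]]
        isiSegs[[length(isiSegs) + 1L]] <- resampleVec(seg, config$isiPoints)
      }
    }
  }
  featC <- if (length(isiSegs)) Reduce(`+`, isiSegs) / length(isiSegs) else
    numeric(config$isiPoints)

  # (d) binned firing rate at rheobase, +40, +80 pA
  binS <- config$binMs / 1000
  supraAmps <- amps[supra]
  rateVecs <- stats::setNames(lapply(supra, function(j) {
    binnedRate(spk[[j]]$times,
               sweeps[[j]]@epochs$offset[1] - sweeps[[j]]@epochs$onset[1],
               binS)
  }), as.character(supraAmps))
  featD <- unlist(lapply(rheo + config$stepOffsets, function(target) {
    hit <- which(abs(supraAmps - target) < 1e-9)
    if (length(hit)) rateVecs[[hit[1]]] else
      interpolateAmp(target, supraAmps, rateVecs)
  }))

  # (e) binned subthreshold responses
  sub <- which(amps < 0)
  if (!length(sub)) return(NULL)
  subAmps <- amps[sub]
  subVecs <- stats::setNames(lapply(sub, function(j) {
    binnedVoltage(sweeps[[j]], config$subBinMs / 1000)
  }), as.character(subAmps))
  featE <- unlist(lapply(config$subAmps, function(target) {
    hit <- which(abs(subAmps - target) < 1e-9)
    if (length(hit)) subVecs[[hit[1]]] else
      interpolateAmp(target, subAmps, subVecs)
  }))

  # (f) largest hyperpolarizing step, min/baseline normalized
  hj <- sub[which.min(amps[sub])]
  hs <- sweeps[[hj]]
  on <- hs@epochs$onset[1]; off <- hs@epochs$offset[1]
  base <- mean(hs@voltage[sampleWindow(hs, max(hs@startTime, on - 0.1), on)])
  idx <- sampleWindow(hs, on, off)
  vmin <- min(hs@voltage[idx])
  featF <- if (base > vmin) {
    resampleVec((hs@voltage[idx] - vmin) / (base - vmin), config$hypPoints)
  } else {
    rep(0, config$hypPoints)
  }

  row <- c(featA, featB, featC, featD, featE, featF)
  if (any(!is.finite(row))) return(NULL)
  attr(row, "category") <- rep(c("a", "b", "c", "d", "e", "f"),
                               c(length(featA), length(featB), length(featC),
                                 length(featD), length(featE), length(featF)))
  row
}
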