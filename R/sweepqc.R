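#' Create a sweep-QC configuration
#'
#' All defaults are the standard acquisition criteria (see
#' [QCConfig-class] for units and bound conventions).
#'
#' @param targetVm target membrane potential, mV.
#' @param rmpTolerance mV; RMP must be within this of target (inclusive).
#' @param baselineWindow ms of pre-stimulus baseline evaluated.
#' @param rmsShortWindow,rmsShortMax short-window RMS criterion (ms, mV).
#' @param rmsLongWindow,rmsLongMax long-window RMS criterion (ms, mV).
#' @param recoveryMin,recoveryEval,recoveryMax recovery assay geometry
#'   (ms, ms, s).
#' @param rampSpikeLimit spikes after which the ramp stimulus is terminated.
#' @param leakLimit pA; inclusive bound on |bias current|.
#' @param bridgeAbsMax,bridgeFracMax bridge-balance bounds (MOhm, fraction of
#'   R_input; strict).
#' @param accessAbsMax,accessFracMax access-resistance bounds (strict).
#' @param sealMin GOhm; pre-break-in seal must exceed this.
#' @param spikeDvdt mV/ms online detection threshold.
#' @param smoothSamples causal boxcar width (samples) for online detection.
#' @param maxBiasStep pA; autobias step clip.
#' @return A [QCConfig-class].
#' @export
qcConfig <- function(targetVm = -70, rmpTolerance = 1, baselineWindow = 500,
                     rmsShortWindow = 1.5, rmsShortMax = 0.07,
                     rmsLongWindow = 500, rmsLongMax = 0.5,
                     recoveryMin = 500, recoveryEval = 500, recoveryMax = 10,
                     rampSpikeLimit = 5L, leakLimit = 100,
                     bridgeAbsMax = 20, bridgeFracMax = 0.15,
                     accessAbsMax = 20, accessFracMax = 0.15, sealMin = 1,
                     spikeDvdt = 20, smoothSamples = 5L, maxBiasStep = 50) {
  new("QCConfig", targetVm = targetVm, rmpTolerance = rmpTolerance,
      baselineWindow = baselineWindow, rmsShortWindow = rmsShortWindow,
      rmsShortMax = rmsShortMax, rmsLongWindow = rmsLongWindow,
      rmsLongMax = rmsLongMax, recoveryMin = recoveryMin,
      recoveryEval = recoveryEval, recoveryMax = recoveryMax,
      rampSpikeLimit = as.integer(rampSpikeLimit), leakLimit = leakLimit,
      bridgeAbsMax = bridgeAbsMax, bridgeFracMax = bridgeFracMax,
      accessAbsMax = accessAbsMax, accessFracMax = accessFracMax,
      sealMin = sealMin, spikeDvdt = spikeDvdt,
      smoothSamples = as.integer(smoothSamples), maxBiasStep = maxBiasStep)
}

#' Per-sweep amplifier metadata
#'
#' @param bridgeBalance MOhm.
#' @param biasCurrent pA.
#' @param sealPreBreakin GOhm.
#' @param accessResistance MOhm.
#' @param inputResistance MOhm (R_input).
#' @return named list (validated: resistances >= 0).
#' @export
sweepMeta <- function(bridgeBalance, biasCurrent, sealPreBreakin,
                      accessResistance, inputResistance) {
  meta <- list(bridgeBalance = bridgeBalance, biasCurrent = biasCurrent,
               sealPreBreakin = sealPreBreakin,
               accessResistance = accessResistance,
               inputResistance = inputResistance)
  bad <- vapply(meta, function(x) is.null(x) || length(x) != 1L || is.na(x),
                logical(1))
  if (any(bad)) {
    stop("missing metadata field(s): ", paste(names(meta)[bad], collapse = ", "))
  }
  res <- c(meta$bridgeBalance, meta$sealPreBreakin, meta$accessResistance,
           meta$inputResistance)
  if (any(res < 0)) stop("resistances must be >= 0")
  meta
}

qcVerdict <- function(reasons, measured) {
  new("QCVerdict", passed = length(reasons) == 0L, reasons = reasons,
      measured = measured)
}

# Baseline metrics on a window of voltage samples.
baselineMetrics <- function(v, dt, cfg) {
  rmp <- mean(v)
  rmsLong <- rmsCentered(v)
  sub <- max(1L, floor(cfg@rmsShortWindow / 1000 / dt))
  nSub <- length(v) %/% sub
  rmsShort <- if (nSub >= 1L) {
    max(vapply(seq_len(nSub), function(k) {
      rmsCentered(v[((k - 1L) * sub + 1L):(k * sub)])
    }, numeric(1)))
  } else rmsLong
  c(rmp = rmp, rms_short = rmsShort, rms_long = rmsLong)
}

windowReasons <- function(met, cfg) {
  reasons <- character()
  if (abs(met[["rmp"]] - cfg@targetVm) > cfg@rmpTolerance) {
    reasons <- c(reasons, "rmp_out_of_range")
  }
  if (!(met[["rms_short"]] < cfg@rmsShortMax)) reasons <- c(reasons, "rms_short")
  if (!(met[["rms_long"]] < cfg@rmsLongMax)) reasons <- c(reasons, "rms_long")
  reasons
}

sampleWindow <- function(sweep, t0, t1) {
  tms <- sweepTimes(sweep)
  which(tms >= t0 - 1e-12 & tms < t1 - 1e-12)
}

#' Evaluate the pre-stimulus baseline of a sweep
#'
#' The baseline window is the \code{baselineWindow} ms immediately preceding
#' the first stimulus epoch (or the first \code{baselineWindow} ms of the
#' sweep if it has no epochs). The sweep passes iff the window's mean voltage
#' is within \code{rmpTolerance} of \code{targetVm} (inclusive), the maximum
#' RMS over non-overlapping mean-subtracted \code{rmsShortWindow} sub-windows
#' is strictly below \code{rmsShortMax}, and the mean-subtracted RMS over the
#' whole window is strictly below \code{rmsLongMax}. Measured metric values
#' are always reported.
#'
#' @param sweep A [VoltageSweep-class].
#' @param cfg A [QCConfig-class].
#' @return A [QCVerdict-class] with \code{measured} entries \code{rmp},
#'   \code{rms_short}, \code{rms_long}.
#' @export
evaluateBaseline <- function(sweep, cfg = qcConfig()) {
  bw <- cfg@baselineWindow / 1000
  t0 <- if (nrow(sweep@epochs)) min(sweep@epochs$onset) else
    sweep@startTime + bw
  if (t0 - bw < sweep@startTime - 1e-12) {
    stop("insufficient pre-stimulus data: need ", cfg@baselineWindow,
         " ms before the first epoch")
  }
  idx <- sampleWindow(sweep, t0 - bw, t0)
  met <- baselineMetrics(sweep@voltage[idx], sweep@dt, cfg)
  qcVerdict(windowReasons(met, cfg), met)
}

#' Evaluate post-stimulus recovery
#'
#' After an enforced \code{recoveryMin} ms minimal recovery period, the RMP
#' is assayed in consecutive \code{recoveryEval} ms windows. The first window
#' whose mean voltage is within tolerance of target (and which passes both
#' RMS criteria) completes the sweep; its end time is the recorded
#' \code{pass_time}. If no window passes before \code{stimEnd + recoveryMax}
#' seconds, the sweep fails with reason \code{"no_recovery"}.
#'
#' @param sweep A [VoltageSweep-class].
#' @param stimEnd stimulus end time, s.
#' @param cfg A [QCConfig-class].
#' @return A [QCVerdict-class]; \code{measured} has \code{rmp} (of the last
#'   evaluated window) and \code{pass_time} (NA on failure).
#' @export
evaluateRecovery <- function(sweep, stimEnd, cfg = qcConfig()) {
  tEnd <- sweep@startTime + sweepDuration(sweep)
  if (stimEnd < sweep@startTime || stimEnd > tEnd + 1e-12) {
    stop("stimEnd outside the sweep")
  }
  if (tEnd < stimEnd + cfg@recoveryMin / 1000 - 1e-12) {
    stop("sweep must extend at least ", cfg@recoveryMin, " ms past stimEnd")
  }
  evalS <- cfg@recoveryEval / 1000
  w0 <- stimEnd + cfg@recoveryMin / 1000
  lastRmp <- NA_real_
  k <- 0L
  repeat {
    t0 <- w0 + k * evalS
    t1 <- t0 + evalS
    if (t1 > stimEnd + cfg@recoveryMax + 1e-12 || t1 > tEnd + 1e-12) break
    idx <- sampleWindow(sweep, t0, t1)
    met <- baselineMetrics(sweep@voltage[idx], sweep@dt, cfg)
    lastRmp <- met[["rmp"]]
    if (length(windowReasons(met, cfg)) == 0L) {
      return(qcVerdict(character(),
                       c(rmp = lastRmp, pass_time = t1)))
    }
    k <- k + 1L
  }
  qcVerdict("no_recovery", c(rmp = lastRmp, pass_time = NA_real_))
}

#' Autobias current adjustment
#'
#' The inter-sweep bias-current correction that brings the measured RMP back
#' to target: Ohm's law on the input resistance,
#' \code{dI = (targetVm - measuredRmp) / R_input}, clipped to
#' \code{+/- maxBiasStep}.
#'
#' @param measuredRmp mV.
#' @param cfg A [QCConfig-class] (provides target and clip).
#' @param meta metadata from [sweepMeta()] (provides \code{inputResistance}).
#' @return adjustment in pA.
#' @examples
#' m <- sweepMeta(10, 0, 1.5, 8, 100)
#' autobiasStep(-68, qcConfig(targetVm = -70), m)  # -20 pA
#' @export
autobiasStep <- function(measuredRmp, cfg, meta) {
  r <- meta$inputResistance
  if (is.null(r) || r <= 0) stop("input resistance must be > 0")
  dI <- (cfg@targetVm - measuredRmp) / r * 1000  # mV / MOhm -> nA -> pA
  max(-cfg@maxBiasStep, min(cfg@maxBiasStep, dI))
}

#' Online spike detection on a voltage trace
#'
#' Computes the causal boxcar-smoothed first derivative (mV/ms) and returns
#' the sample indices of its local maxima that exceed \code{thresholdDvdt}.
#' Using excursion maxima rather than raw threshold crossings makes the event
#' set monotone in the threshold: raising it always yields a subset.
#'
#' @param voltage mV.
#' @param dt s.
#' @param thresholdDvdt mV/ms (strict bound).
#' @param smoothSamples causal boxcar width.
#' @return integer sample indices, increasing.
#' @export
detectSpikesOnline <- function(voltage, dt, thresholdDvdt = 20,
                               smoothSamples = 5L) {
  n <- length(voltage)
  if (n < 3L) stop("need at least 3 samples")
  d <- c(0, diff(voltage)) / (dt * 1000)
  s <- as.numeric(stats::filter(d, rep(1 / smoothSamples, smoothSamples),
                                sides = 1))
  s[is.na(s)] <- 0
  above <- s > thresholdDvdt
  # first sample of each plateau-or-peak local maximum above threshold
  lm <- which(above &
                s > c(-Inf, s[-n]) &
                s >= c(s[-1], -Inf))
  lm
}

#' Sweep inclusion from amplifier metadata
#'
#' A sweep is included iff the bridge balance is below both the absolute
#' bound and the stated fraction of R_input, the bias (leak) current is
#' within \code{+/- leakLimit} pA, and the baseline RMS criteria were met.
#'
#' @param meta metadata from [sweepMeta()].
#' @param baselineVerdict the [QCVerdict-class] from [evaluateBaseline()].
#' @param cfg A [QCConfig-class].
#' @return A [QCVerdict-class].
#' @export
sweepInclusion <- function(meta, baselineVerdict, cfg = qcConfig()) {
  reasons <- character()
  if (!(meta$bridgeBalance < cfg@bridgeAbsMax)) {
    reasons <- c(reasons, "bridge_abs")
  }
  if (!(meta$bridgeBalance < cfg@bridgeFracMax * meta$inputResistance)) {
    reasons <- c(reasons, "bridge_frac")
  }
  if (abs(meta$biasCurrent) > cfg@leakLimit) reasons <- c(reasons, "leak")
  rmsFail <- intersect(baselineVerdict@reasons, c("rms_short", "rms_long"))
  reasons <- c(reasons, rmsFail)
  qcVerdict(reasons, c(bridge = meta$bridgeBalance, bias = meta$biasCurrent,
                       baselineVerdict@measured))
}

#' Cell inclusion from seal and access metadata
#'
#' A cell is included iff the pre-break-in seal exceeds \code{sealMin} GOhm
#' and the initial access resistance is below both the absolute bound and
#' the stated fraction of R_input.
#'
#' @param meta metadata from [sweepMeta()].
#' @param cfg A [QCConfig-class].
#' @return A [QCVerdict-class].
#' @export
cellInclusion <- function(meta, cfg = qcConfig()) {
  reasons <- character()
  if (!(meta$sealPreBreakin > cfg@sealMin)) reasons <- c(reasons, "seal")
  if (!(meta$accessResistance < cfg@accessAbsMax)) {
    reasons <- c(reasons, "access_abs")
  }
  if (!(meta$accessResistance < cfg@accessFracMax * meta$inputResistance)) {
    reasons <- c(reasons, "access_frac")
  }
  qcVerdict(reasons, c(seal = meta$sealPreBreakin,
                       access = meta$accessResistance,
                       r_input = meta$inputResistance))
}
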