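#' Run a stimulus set with online QC, repeats and abort logic
#'
#' Acquires the sweeps of a stimulus set from a responder, applying baseline
#' and recovery QC to each. Failed sweeps are repeated. The set aborts exactly
#' when the remaining required passes plus the accumulated failures exceed
#' the total sweep allotment (\code{required + maxRepeats}; the default
#' \code{maxRepeats = required} makes the allotment twice the set size, i.e.
#' acquisition stops once failures make completion impossible).
#'
#' On ramp sweeps the stimulus is terminated online: the full ramp is
#' acquired, spikes are detected causally with [detectSpikesOnline()], and if
#' \code{cfg@rampSpikeLimit} spikes occur before the programmed offset, the
#' epoch is truncated at the limiting spike's time and the sweep re-acquired
#' with the shortened stimulus; recording continues through the recovery
#' period.
#'
#' @param responder either a [MembraneSpec-class] (sweeps are simulated with
#'   [makeSweep()]) or a \code{function(epochs, attempt)} returning a
#'   [VoltageSweep-class].
#' @param templates list of epoch tables (see [stimulusEpoch()]), one per
#'   required sweep.
#' @param cfg A [QCConfig-class].
#' @param seed integer, split per attempt for simulated responders.
#' @param maxRepeats extra sweeps allowed beyond the set size.
#' @param duration sweep length passed to simulated responders, s.
#' @return list with \code{sweeps} (passing sweeps), \code{verdicts} (per
#'   attempt), \code{failures} (count), \code{attempts} (count) and
#'   \code{aborted} (flag).
#' @export
runStimulusSet <- function(responder, templates, cfg = qcConfig(),
                           seed = 1L, maxRepeats = length(templates),
                           duration = NULL) {
  if (!length(templates)) stop("template list must be non-empty")
  if (is(responder, "MembraneSpec")) {
    m <- responder
    responder <- function(epochs, attempt) {
      makeSweep(m, epochs, seed = childSeed(seed, attempt),
                duration = duration)
    }
  }
  required <- length(templates)
  total <- required + maxRepeats
  passed <- list()
  verdicts <- list()
  failures <- 0L
  attempt <- 0L
  aborted <- FALSE
  i <- 1L
  while (i <= required) {
    remaining <- required - length(passed)
    if (remaining + failures > total) {
      aborted <- TRUE
      break
    }
    attempt <- attempt + 1L
    epochs <- templates[[i]]
    sweep <- responder(epochs, attempt)
    if (any(epochs$kind == "ramp")) {
      sweep <- terminateRamp(sweep, responder, attempt, cfg)
      epochs <- sweep@epochs
    }
    vb <- evaluateBaseline(sweep, cfg)
    if (vb@passed) {
      stimEnd <- max(epochs$offset)
      vr <- evaluateRecovery(sweep, stimEnd, cfg)
      verdict <- qcVerdict(vr@reasons, c(vb@measured, vr@measured))
    } else {
      verdict <- vb
    }
    verdicts[[attempt]] <- verdict
    if (verdict@passed) {
      passed[[length(passed) + 1L]] <- sweep
      i <- i + 1L
    } else {
      failures <- failures + 1L
    }
  }
  if (!aborted && length(passed) < required) aborted <- TRUE
  list(sweeps = passed, verdicts = verdicts, failures = failures,
       attempts = attempt, aborted = aborted)
}

# Truncate a ramp epoch at the configured spike count and re-acquire.
terminateRamp <- function(sweep, responder, attempt, cfg) {
  ep <- sweep@epochs
  k <- which(ep$kind == "ramp")[1]
  idx <- sampleWindow(sweep, ep$onset[k], ep$offset[k])
  ev <- detectSpikesOnline(sweep@voltage[idx], sweep@dt, cfg@spikeDvdt,
                           cfg@smoothSamples)
  if (length(ev) < cfg@rampSpikeLimit) return(sweep)
  tms <- sweepTimes(sweep)[idx]
  tcut <- tms[ev[cfg@rampSpikeLimit]]
  ep$offset[k] <- tcut
  responder(ep, attempt)
}
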