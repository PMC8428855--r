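#' Piecewise-linear action-potential template
#'
#' A rise of exactly \code{peakDvdt} mV/ms from 0 to \code{height}, a linear
#' fall to \code{ahp} at \code{fallDvdt} mV/ms, and a linear return to 0. The
#' piecewise-linear shape gives analytic control of every derivative feature,
#' so detector boundaries can be tested exactly.
#'
#' @param peakDvdt rise slope, mV/ms (the template's maximum dV/dt).
#' @param height peak height above the insertion voltage, mV.
#' @param fallDvdt fall slope magnitude, mV/ms.
#' @param ahp after-hyperpolarization depth below insertion voltage, mV (>= 0).
#' @param recoverMs duration of the linear return from the AHP to 0, ms.
#' @param samplingRate kHz.
#' @return numeric waveform in mV relative to the insertion voltage, with
#'   attribute \code{peakDvdt}.
#' @export
apTemplateWave <- function(peakDvdt = 100, height = 60, fallDvdt = peakDvdt / 3,
                           ahp = 5, recoverMs = 2, samplingRate = 50) {
  dtms <- 1 / samplingRate
  rise <- seq(0, height, by = peakDvdt * dtms)
  fall <- seq(height, -ahp, by = -fallDvdt * dtms)[-1]
  rec <- if (ahp > 0 && recoverMs > 0) {
    seq(-ahp, 0, length.out = max(2L, round(recoverMs / dtms)))[-1]
  } else 0
  w <- c(rise, fall, rec)
  attr(w, "peakDvdt") <- peakDvdt
  w
}

#' Construct a membrane model specification
#'
#' @param rmp resting potential, mV.
#' @param rInput input resistance, MOhm.
#' @param tau membrane time constant, ms.
#' @param spikeThreshold spike threshold, mV; \code{Inf} for a passive cell.
#' @param apTemplate spike waveform from [apTemplateWave()] (or any numeric
#'   waveform starting at 0, in mV relative to threshold crossing).
#' @param noiseRms additive white measurement-noise RMS, mV.
#' @param driftRate linear baseline drift, mV/s.
#' @param samplingRate kHz.
#' @return A [MembraneSpec-class].
#' @export
membraneSpec <- function(rmp = -70, rInput = 100, tau = 10,
                         spikeThreshold = Inf,
                         apTemplate = apTemplateWave(samplingRate = samplingRate),
                         noiseRms = 0, driftRate = 0, samplingRate = 50) {
  pk <- attr(apTemplate, "peakDvdt")
  if (is.null(pk)) {
    pk <- max(diff(apTemplate)) * samplingRate
  }
  new("MembraneSpec", rmp = rmp, rInput = rInput, tau = tau,
      spikeThreshold = spikeThreshold, apTemplate = as.numeric(apTemplate),
      apPeakDvdt = pk, noiseRms = noiseRms, driftRate = driftRate,
      samplingRate = samplingRate)
}

#' Build a stimulus-epoch table
#'
#' @param kind "short_pulse", "long_square" or "ramp".
#' @param onset,offset seconds.
#' @param amplitude pA (for a ramp: slope in pA/s, default 25).
#' @return data.frame usable as the \code{epochs} slot of a sweep.
#' @export
stimulusEpoch <- function(kind, onset, offset, amplitude = if (kind == "ramp") 25 else 0) {
  data.frame(kind = kind, onset = onset, offset = offset,
             amplitude = amplitude, stringsAsFactors = FALSE)
}

# Stimulus waveform (pA) for an epoch table on a uniform time grid.
stimulusTrace <- function(epochs, times) {
  stim <- numeric(length(times))
  for (k in seq_len(nrow(epochs))) {
    inside <- times >= epochs$onset[k] & times < epochs$offset[k]
    stim[inside] <- if (epochs$kind[k] == "ramp") {
      epochs$amplitude[k] * (times[inside] - epochs$onset[k])
    } else {
      epochs$amplitude[k]
    }
  }
  stim
}

#' Simulate a current-clamp sweep
#'
#' Integrates the first-order membrane equation exactly on the sampling grid
#' (\code{V -> Vinf + (V - Vinf) exp(-dt/tau)} with
#' \code{Vinf = rmp + rInput * I}); whenever the trajectory reaches
#' \code{spikeThreshold} the AP template is pasted in and integration resumes
#' from the template's end. Measurement noise and linear drift are added to
#' the recorded trace after integration, so spike timing is a deterministic
#' function of the stimulus.
#'
#' @param m A [MembraneSpec-class].
#' @param epochs data.frame of stimulus epochs (see [stimulusEpoch()]);
#'   non-overlapping and within the sweep.
#' @param seed integer, for the measurement noise.
#' @param duration sweep length, s (default: last epoch offset + 1 s).
#' @param startTime sweep start, s.
#' @return A [VoltageSweep-class].
#' @examples
#' m <- membraneSpec(rInput = 100)
#' sw <- makeSweep(m, stimulusEpoch("long_square", 0.5, 1.5, -70),
#'                 duration = 2)
#' @export
makeSweep <- function(m, epochs, seed = 1L, duration = NULL, startTime = 0) {
  validObject(m)
  if (is.null(duration)) {
    duration <- if (nrow(epochs)) max(epochs$offset) - startTime + 1 else 1
  }
  dt <- 1 / (m@samplingRate * 1000)
  n <- round(duration / dt)
  times <- startTime + (seq_len(n) - 1) * dt
  if (nrow(epochs)) {
    if (any(epochs$onset < startTime - 1e-12) ||
        any(epochs$offset > startTime + duration + 1e-9)) {
      stop("stimulus epoch outside the sweep")
    }
    ep <- epochs[order(epochs$onset), , drop = FALSE]
    if (nrow(ep) > 1 && any(ep$onset[-1] < ep$offset[-nrow(ep)] - 1e-12)) {
      stop("stimulus epochs overlap")
    }
  }
  stim <- stimulusTrace(epochs, times)

  a <- exp(-dt / (m@tau / 1000))
  vinf <- m@rmp + m@rInput * stim / 1000  # pA * MOhm = uV*... (pA*MOhm = 1e-6 V) -> mV via /1000

  v <- numeric(n)
  tpl <- m@apTemplate
  if (is.infinite(m@spikeThreshold)) {
    # fast path: linear recursion, no spikes possible
    v <- as.numeric(stats::filter((1 - a) * vinf, a, method = "recursive",
                                  init = m@rmp))
    v <- c(m@rmp, v[-n])
  } else {
    v[1] <- m@rmp
    i <- 1L
    while (i < n) {
      nxt <- vinf[i] + (v[i] - vinf[i]) * a
      if (nxt >= m@spikeThreshold) {
        nxt <- m@spikeThreshold
        idx <- i + seq_along(tpl)
        idx <- idx[idx <= n]
        v[idx] <- nxt + tpl[seq_along(idx)]
        i <- i + length(idx)
        next
      }
      v[i + 1L] <- nxt
      i <- i + 1L
    }
  }
  if (m@noiseRms > 0) {
    v <- v + withSeed(seed, stats::rnorm(n, 0, m@noiseRms))
  }
  if (m@driftRate != 0) v <- v + m@driftRate * (times - startTime)
  new("VoltageSweep", startTime = startTime, dt = dt, voltage = v,
      stimulus = stim, epochs = epochs)
}

#' @describeIn VoltageSweep-class the sample time grid, seconds.
#' @param sweep A \code{VoltageSweep}.
#' @export
sweepTimes <- function(sweep) {
  sweep@startTime + (seq_along(sweep@voltage) - 1) * sweep@dt
}

#' @describeIn VoltageSweep-class sweep duration, seconds.
#' @export
sweepDuration <- function(sweep) length(sweep@voltage) * sweep@dt
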