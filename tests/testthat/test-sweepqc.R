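cfg70 <- qcConfig(targetVm = -70)

test_that("baseline evaluation enforces RMP and RMS criteria", {
  expect_true(qcPassed(evaluateBaseline(flatSweep(-70), cfg70)))
  v2 <- evaluateBaseline(flatSweep(-72), cfg70)
  expect_false(qcPassed(v2))
  expect_identical(qcReasons(v2), "rmp_out_of_range")
  expect_equal(qcMeasured(v2)[["rmp"]], -72)
  # insufficient pre-stimulus data
  early <- flatSweep(-70, epochs = stimulusEpoch("long_square", 0.2, 0.3, 0))
  expect_error(evaluateBaseline(early, cfg70), "insufficient")
})

test_that("square-wave noise trips the RMS criteria at its exact RMS", {
  # a zero-mean +/-a square wave has RMS exactly a; dt chosen so the 1.5 ms
  # sub-windows hold an even sample count and the wave is exactly zero-mean
  mkNoisy <- function(a, whole = TRUE) {
    sw <- flatSweep(-70, dt = 5e-5)
    idx <- sampleWindow(sw, 0.1, 0.6)  # the 500 ms baseline window
    if (!whole) idx <- idx[1:30]       # one 1.5 ms sub-window
    sw@voltage[idx] <- sw@voltage[idx] + a * rep(c(1, -1), length(idx) / 2)
    sw
  }
  a <- 2 * cfg70@rmsLongMax
  v <- evaluateBaseline(mkNoisy(a), cfg70)
  expect_false(qcPassed(v))
  expect_true("rms_long" %in% qcReasons(v))
  expect_equal(qcMeasured(v)[["rms_long"]], a, tolerance = 1e-12)
  # short-window criterion sees a burst confined to one sub-window
  vs <- evaluateBaseline(mkNoisy(0.1, whole = FALSE), cfg70)
  expect_false(qcPassed(vs))
  expect_true("rms_short" %in% qcReasons(vs))
  expect_equal(qcMeasured(vs)[["rms_short"]], 0.1, tolerance = 1e-12)
  # below both bounds passes
  expect_true(qcPassed(evaluateBaseline(mkNoisy(0.05), cfg70)))
})

test_that("baseline pass region is the product of the three criteria", {
  for (off in c(0, 0.8, 1.2)) {
    for (a in c(0.02, 0.4, 0.6)) {
      sw <- flatSweep(-70 + off, dt = 1e-4)
      idx <- sampleWindow(sw, 0.1, 0.6)
      sw@voltage[idx] <- sw@voltage[idx] + a * rep(c(1, -1), length(idx) / 2)
      v <- evaluateBaseline(sw, cfg70)
      shortOk <- a < cfg70@rmsShortMax
      expected <- (abs(off) <= cfg70@rmpTolerance) &&
        (a < cfg70@rmsLongMax) && shortOk
      expect_identical(qcPassed(v), expected)
    }
  }
})

test_that("recovery assay finds the first recovered 500 ms window", {
  mkRec <- function(recoverAt, level = -75, duration = 12) {
    dt <- 2e-4
    n <- round(duration / dt)
    tt <- (seq_len(n) - 1) * dt
    v <- ifelse(tt < 1.6 + recoverAt, level, -70)
    new("VoltageSweep", startTime = 0, dt = dt, voltage = v,
        stimulus = numeric(n),
        epochs = stimulusEpoch("long_square", 0.6, 1.6, 0))
  }
  # immediate recovery: pass_time = stimEnd + 0.5 + 0.5
  v0 <- evaluateRecovery(mkRec(0), 1.6, cfg70)
  expect_true(qcPassed(v0))
  expect_equal(qcMeasured(v0)[["pass_time"]], 2.6)
  # recovery at stimEnd + 2.3 s: windows [0.5,1.0], [1.0,1.5], ... relative
  # to stimEnd; the first fully recovered one ends at stimEnd + 3.0
  v23 <- evaluateRecovery(mkRec(2.3), 1.6, cfg70)
  expect_true(qcPassed(v23))
  expect_equal(qcMeasured(v23)[["pass_time"]], 1.6 + 3.0)
  # a 5 mV offset for the whole 10 s tail exhausts the assay
  vFail <- evaluateRecovery(mkRec(99), 1.6, cfg70)
  expect_false(qcPassed(vFail))
  expect_identical(qcReasons(vFail), "no_recovery")
  expect_true(is.na(qcMeasured(vFail)[["pass_time"]]))
  # pass_time is always stimEnd + recoveryMin + k * recoveryEval, within max
  for (r in c(0.7, 1.4, 3.9)) {
    pt <- qcMeasured(evaluateRecovery(mkRec(r), 1.6, cfg70))[["pass_time"]]
    k <- (pt - 1.6 - 0.5) / 0.5
    expect_equal(k, round(k))
    expect_lte(pt, 1.6 + cfg70@recoveryMax)
  }
  expect_error(evaluateRecovery(mkRec(0), 99), "outside")
})

test_that("autobias follows Ohm's law with a clipped step", {
  meta <- sweepMeta(10, 0, 1.5, 8, 100)
  expect_equal(autobiasStep(-70, cfg70, meta), 0)
  expect_equal(autobiasStep(-68, cfg70, meta), -20)
  expect_equal(autobiasStep(-20, cfg70, meta), -cfg70@maxBiasStep)
  expect_equal(autobiasStep(-120, cfg70, meta), cfg70@maxBiasStep)
  badMeta <- sweepMeta(10, 0, 1.5, 8, 100)
  badMeta$inputResistance <- 0
  expect_error(autobiasStep(-68, cfg70, badMeta), "input resistance")
})

test_that("sweep and cell inclusion implement the resistance rules", {
  base <- qcPassed(evaluateBaseline(flatSweep(-70), cfg70))
  okBase <- evaluateBaseline(flatSweep(-70), cfg70)
  expect_true(base)
  fail <- function(meta) !qcPassed(sweepInclusion(meta, okBase, cfg70))
  expect_true(fail(sweepMeta(25, 0, 1.5, 8, 300)))      # absolute bridge
  expect_true(fail(sweepMeta(10, -120, 1.5, 8, 300)))   # leak
  expect_true(fail(sweepMeta(10, 0, 1.5, 8, 50)))       # 10/50 = 20% > 15%
  expect_true(qcPassed(sweepInclusion(sweepMeta(10, 100, 1.5, 8, 300),
                                      okBase, cfg70)))  # |bias| = 100 passes
  expect_true(qcPassed(cellInclusion(sweepMeta(5, 0, 1.5, 10, 150), cfg70)))
  expect_false(qcPassed(cellInclusion(sweepMeta(5, 0, 0.8, 10, 150), cfg70)))
  expect_false(qcPassed(cellInclusion(sweepMeta(5, 0, 1.5, 18, 100), cfg70)))
  expect_error(sweepMeta(5, 0, NA, 10, 150), "missing")
})

test_that("online spike detection is causal and monotone in threshold", {
  tr <- traceWithTemplate(40)   # peak dV/dt = 2 x the 20 mV/ms threshold
  expect_length(detectSpikesOnline(tr$voltage, tr$dt, 20), 1)
  trLow <- traceWithTemplate(10)  # 0.5 x threshold
  expect_length(detectSpikesOnline(trLow$voltage, trLow$dt, 20), 0)
  # two templates 50 ms apart
  v <- rep(-70, 4000)
  tpl <- apTemplateWave(peakDvdt = 40, samplingRate = 10)
  v[1000 + seq_along(tpl) - 1] <- -70 + tpl
  v[1500 + seq_along(tpl) - 1] <- -70 + tpl
  ev <- detectSpikesOnline(v, 1e-4, 20)
  expect_length(ev, 2)
  expect_true(all(diff(ev) > 0))
  # monotone-subset property on rough random traces
  for (sd in 1:5) {
    set.seed(sd)
    vr <- cumsum(rnorm(2000, 0, 0.5))
    prev <- NULL
    for (thr in c(2, 5, 10, 20)) {
      evr <- detectSpikesOnline(vr, 1e-4, thr)
      if (!is.null(prev)) expect_true(all(evr %in% prev))
      prev <- evr
    }
  }
})

test_that("stimulus sets repeat failures and abort by the counting rule", {
  passResponder <- function(epochs, attempt) {
    makeSweep(membraneSpec(rmp = -70, samplingRate = 5), epochs,
              duration = max(epochs$offset) + 1.2)
  }
  templates <- rep(list(stimulusEpoch("long_square", 0.6, 1.6, 0)), 3)
  ok <- runStimulusSet(passResponder, templates, cfg70)
  expect_false(ok$aborted)
  expect_identical(ok$attempts, 3L)
  expect_identical(ok$failures, 0L)
  expect_length(ok$sweeps, 3)
  # always failing baseline: allotment is 2 x 3 = 6; abort once
  # remaining(3) + failures(4) > 6
  failResponder <- function(epochs, attempt) {
    makeSweep(membraneSpec(rmp = -60, samplingRate = 5), epochs,
              duration = max(epochs$offset) + 1.2)
  }
  bad <- runStimulusSet(failResponder, templates, cfg70)
  expect_true(bad$aborted)
  expect_identical(bad$failures, 4L)
  expect_identical(bad$attempts, 4L)
  # one transient failure then passing: templates + 1 attempts, set passes
  flaky <- function(epochs, attempt) {
    if (attempt == 1) failResponder(epochs, attempt) else
      passResponder(epochs, attempt)
  }
  f <- runStimulusSet(flaky, templates, cfg70)
  expect_false(f$aborted)
  expect_identical(f$attempts, 4L)
  expect_length(f$sweeps, 3)
  expect_error(runStimulusSet(passResponder, list(), cfg70), "non-empty")
})

test_that("ramp stimulus is terminated online after the spike limit", {
  m <- spikingMembrane()
  ramp <- stimulusEpoch("ramp", 0.6, 4.6, 25)
  res <- runStimulusSet(m, list(ramp), cfg70, duration = 7)
  expect_false(res$aborted)
  sw <- res$sweeps[[1]]
  # the stimulus was shortened and the recorded trace holds exactly 5 spikes
  expect_lt(sw@epochs$offset[1], 4.6)
  ev <- detectSpikesOnline(sw@voltage, sw@dt, cfg70@spikeDvdt)
  expect_identical(length(ev), 5L)
  expect_true(all(sweepTimes(sw)[ev] <= sw@epochs$offset[1] + 1e-9))
  # deterministic responder gives a deterministic set
  res2 <- runStimulusSet(m, list(ramp), cfg70, duration = 7)
  expect_identical(sw@voltage, res2$sweeps[[1]]@voltage)
})
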