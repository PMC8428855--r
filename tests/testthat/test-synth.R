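test_that("reference generation is deterministic and CPM-normalized", {
  cfg <- synthConfig(seed = 5, nClasses = 3, typesPerClass = 2, nGenes = 400,
                     markersPerClass = 15, markersPerType = 6,
                     nRefCellsPerType = 8)
  t1 <- makeReference(cfg)
  t2 <- makeReference(cfg)
  expect_identical(t1@exprs, t2@exprs)
  expect_identical(t1@typeMeans, t2@typeMeans)
  expect_true(all(is.finite(t1@exprs)) && all(t1@exprs >= 0))
  # per-cell linear CPM sums to 1e6 before the log transform
  expect_equal(colSums(2^t1@exprs - 1), rep(1e6, ncol(t1@exprs)),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(colSums(2^t1@typeMeans - 1), rep(1e6, ncol(t1@typeMeans)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthConfig(nClasses = 0), "counts")
  expect_error(synthConfig(markerEffect = -1), "markerEffect")
  expect_error(synthConfig(nGenes = 10), "disjoint marker blocks")
  expect_error(synthConfig(gliaClasses = 4, nClasses = 4), "gliaClasses")
})

test_that("planted class markers have the largest class-vs-rest mean difference", {
  tax <- makeReference(synthConfig(seed = 21, nClasses = 3, typesPerClass = 2,
                                   nGenes = 400, markersPerClass = 20,
                                   markersPerType = 5,
                                   nRefCellsPerType = 12))
  cellClass <- tax@classOf[tax@cellType]
  classes <- names(tax@isGlia)
  for (cl in classes) {
    # brute-force group means straight from the expression matrix
    inMean <- rowMeans(tax@exprs[, cellClass == cl])
    outMean <- rowMeans(tax@exprs[, cellClass != cl])
    top <- names(sort(inMean - outMean, decreasing = TRUE))[1:20]
    expect_setequal(top, tax@plantedMarkers$class[[cl]])
  }
})

test_that("marker effect zero leaves class mean profiles equal up to noise", {
  tax <- makeReference(synthConfig(seed = 8, nClasses = 2, typesPerClass = 1,
                                   nGenes = 300, markersPerClass = 20,
                                   markersPerType = 1, markerEffect = 0,
                                   typeEffect = 0, nRefCellsPerType = 25,
                                   noiseSd = 0.1, gliaClasses = 0))
  cellClass <- tax@classOf[tax@cellType]
  classes <- names(tax@isGlia)
  m1 <- rowMeans(tax@exprs[, cellClass == classes[1]])
  m2 <- rowMeans(tax@exprs[, cellClass == classes[2]])
  markers <- unlist(tax@plantedMarkers$class)
  # near the dropout floor the group means are noisy; the planted 4-unit
  # effect of a default reference is absent
  expect_lt(max(abs((m1 - m2)[markers])), 1)
})

test_that("patch-seq cells follow the linear-CPM mixture arithmetic", {
  tax <- smallTax()
  lf <- leafTypes(tax)[1]
  specs <- cellSimSpec(rep(lf, 3), qualityFactor = c(1, 0, 1),
                       contaminationFraction = c(0, 0, 0.5))
  out <- makePatchseqCells(tax, specs, seed = 2, noiseSd = 0)
  # qf = 1, no contamination, no noise: exactly the type mean profile
  expect_equal(out$exprs[, 1], tax@typeMeans[, lf], ignore_attr = TRUE)
  # qf = 0: nothing detected
  expect_true(all(out$exprs[, 2] == 0))
  # 50% glial mixture: direct arithmetic oracle, and glia-marker mean
  # strictly between the pure-type and pure-glia values
  typeCPM <- 2^tax@typeMeans[, lf] - 1
  gl <- leafTypes(tax)[tax@classOf[leafTypes(tax)] == "G1"]
  gliaCPM <- rowMeans(2^tax@typeMeans[, gl] - 1)
  expect_equal(out$exprs[, 3], log2(typeCPM + 0.5 * gliaCPM + 1),
               ignore_attr = TRUE)
  gm <- tax@plantedMarkers$class$G1
  pureType <- mean(log2(typeCPM[gm] + 1))
  pureGlia <- mean(log2(gliaCPM[gm] + 1))
  mixed <- mean(out$exprs[gm, 3])
  expect_gt(mixed, pureType)
  expect_lt(mixed, pureGlia)
  # truth table retains the spec fields
  expect_identical(out$truth$qualityFactor, specs$qualityFactor)
  # unknown type errors
  expect_error(makePatchseqCells(tax, cellSimSpec("nope"), seed = 1),
               "unknown leaf type")
})

test_that("sweep generator obeys Ohm's law and is quiet at rest", {
  m <- membraneSpec(rmp = -70, rInput = 100, tau = 10, samplingRate = 10)
  sw <- makeSweep(m, stimulusEpoch("long_square", 0.5, 1.5, -70),
                  duration = 2)
  late <- sampleWindow(sw, 1.4, 1.5)
  expect_equal(mean(sw@voltage[late]), -77, tolerance = 1e-6)
  # zero stimulus, zero noise, zero drift: constant at rmp
  sw0 <- makeSweep(m, stimulusEpoch("long_square", 0.5, 1.5, 0),
                   duration = 2)
  expect_true(all(abs(sw0@voltage - (-70)) < 1e-12))
  # noise-free subthreshold dV/dt stays below any spike threshold
  s <- smoothedDvdt(sw@voltage, sw@dt)
  expect_lt(max(abs(s)), 20)
  # epoch outside sweep is a bounds error
  expect_error(makeSweep(m, stimulusEpoch("long_square", 0.5, 3, 0),
                         duration = 2), "outside")
})

test_that("ramp spikes are ordered and the first matches the closed-form crossing", {
  m <- spikingMembrane()
  ramp <- stimulusEpoch("ramp", 0.5, 6.5, 25)
  sw <- makeSweep(m, ramp, duration = 7)
  ev <- detectSpikesOnline(sw@voltage, sw@dt, 20)
  expect_gt(length(ev), 2)
  expect_true(all(diff(ev) > 0))
  # closed form for a ramp drive: V(t) = rmp + R*s*(t - tau(1 - e^{-t/tau}))
  tauS <- 15 / 1000
  vAnalytic <- function(t) {
    -70 + 200 * 25 / 1000 * (t - tauS * (1 - exp(-t / tauS)))
  }
  tCross <- uniroot(function(t) vAnalytic(t) - (-55), c(0.01, 6))$root
  tFirst <- sweepTimes(sw)[ev[1]] - 0.5
  expect_equal(tFirst, tCross, tolerance = 0.01)
})

test_that("metadata endR separation matches its analytic AUC target", {
  meta <- makeMetadata(5000, aucTarget = 0.8, seed = 4)
  good <- meta$morphologyOutcome %in% c("high", "medium")
  keep <- good | meta$morphologyOutcome == "failed"
  expect_equal(rocAuc(meta$endPipetteResistance[keep], good[keep])@auc, 0.8,
               tolerance = 0.02)
  # no separation
  m5 <- makeMetadata(10000, aucTarget = 0.5, seed = 6)
  good5 <- m5$morphologyOutcome %in% c("high", "medium")
  keep5 <- good5 | m5$morphologyOutcome == "failed"
  expect_equal(rocAuc(m5$endPipetteResistance[keep5], good5[keep5])@auc, 0.5,
               tolerance = 0.02)
  # disjoint supports
  m1 <- makeMetadata(500, aucTarget = 1, seed = 7)
  good1 <- m1$morphologyOutcome %in% c("high", "medium")
  keep1 <- good1 | m1$morphologyOutcome == "failed"
  expect_equal(rocAuc(m1$endPipetteResistance[keep1], good1[keep1])@auc, 1)
  # cDNA metrics track the nucleus outcome
  expect_gt(mean(meta$cdnaQuantity[meta$nucleusPlus]),
            mean(meta$cdnaQuantity[!meta$nucleusPlus]))
  expect_error(makeMetadata(10, aucTarget = 0.4), "aucTarget")
  expect_identical(makeMetadata(100, 0.8, seed = 3),
                   makeMetadata(100, 0.8, seed = 3))
})
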