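test_that("detection recovers inserted templates around the dV/dt threshold", {
  countAPs <- function(d) {
    tr <- traceWithTemplate(d)
    nrow(detectAPs(tr$voltage, tr$dt))
  }
  expect_identical(countAPs(30), 1L)   # 1.5 x threshold
  expect_identical(countAPs(10), 0L)   # 0.5 x threshold
  expect_identical(countAPs(40), 1L)
  # slow depolarizing bump, max dV/dt ~ 10 mV/ms
  dt <- 1e-4
  bump <- -70 + 20 * exp(-((seq_len(5000) - 2500) * dt * 1000)^2 / 8)
  expect_identical(nrow(detectAPs(bump, dt)), 0L)
  # spikelet below the minimal height is rejected by refinement
  tr <- traceWithTemplate(40, height = 1)
  expect_identical(nrow(detectAPs(tr$voltage, tr$dt)), 0L)
})

test_that("the refined threshold sits at 5% of the average maximal dV/dt", {
  # rising-phase dV/dt increases linearly from 0 to M (quadratic voltage),
  # so the crossing level is analytically controlled
  fs <- 500; dt <- 1 / (fs * 1000); M <- 50; riseMs <- 5
  nR <- riseMs / 1000 / dt
  tms <- seq_len(nR) * dt * 1000
  rise <- -70 + (M / (2 * riseMs)) * tms^2
  fall <- seq(rise[length(rise)], -75, by = -M / 3 * dt * 1000)
  v <- c(rep(-70, 2000), rise, fall, rep(-75, 2000))
  ap <- detectAPs(v, dt)
  expect_identical(nrow(ap), 1L)
  s <- smoothedDvdt(v, dt)
  ratio <- s[ap$thresholdIndex[1]] / max(s)
  expect_equal(ratio, 0.05, tolerance = 0.01)
  # two identical APs: identical relative threshold positions (falls return
  # to the -70 baseline so both events have identical context)
  fall <- seq(rise[length(rise)], -70, by = -M / 3 * dt * 1000)
  v <- c(rep(-70, 2000), rise, fall, rep(-70, 2000))
  ap <- detectAPs(v, dt)
  v2 <- c(rep(-70, 2000), rise, fall, rep(-70, 3000), rise, fall,
          rep(-70, 2000))
  ap2 <- detectAPs(v2, dt)
  expect_identical(nrow(ap2), 2L)
  expect_identical(ap2$thresholdIndex[1] - ap2$detectIndex[1],
                   ap2$thresholdIndex[2] - ap2$detectIndex[2])
  # the 5% rule is a ratio: scaling the trace leaves the index unchanged
  apScaled <- detectAPs(v * 2, dt)
  expect_identical(apScaled$thresholdIndex, ap$thresholdIndex)
})

test_that("shape features follow triangle geometry", {
  dt <- 1e-5
  mkTriangle <- function(riseN, fallN, height = 40, base = 0) {
    v <- rep(base, 6000)
    seg <- c(seq(base, base + height, length.out = riseN + 1),
             seq(base + height, base, length.out = fallN + 1)[-1])
    v[2000:(2000 + length(seg) - 1)] <- seg
    v
  }
  # symmetric triangle: ratio 1
  apS <- detectAPs(mkTriangle(100, 100), dt)
  expect_equal(apS$upstrokeDownstrokeRatio, 1, tolerance = 1e-6)
  # rise 0 -> 40 mV in 1 ms, fall in 2 ms: ratio 2, width 1.5 ms
  apT <- detectAPs(mkTriangle(100, 200), dt)
  expect_equal(apT$upstrokeDownstrokeRatio, 2, tolerance = 1e-6)
  expect_equal(apT$widthHalfHeight, 1.5, tolerance = 0.02)
  expect_equal(apT$upstroke, 40, tolerance = 1e-6)
  expect_equal(apT$downstroke, -20, tolerance = 1e-6)
  # the peak is the trace maximum inside the event window
  expect_equal(apT$peakV, 40, tolerance = 1e-9)
  # ratio is invariant to additive offsets and uniform time scaling
  apOff <- detectAPs(mkTriangle(100, 200, base = -64), dt)
  expect_equal(apOff$upstrokeDownstrokeRatio,
               apT$upstrokeDownstrokeRatio, tolerance = 1e-6)
  apTime <- detectAPs(mkTriangle(200, 400), dt / 2)
  expect_equal(apTime$upstrokeDownstrokeRatio,
               apT$upstrokeDownstrokeRatio, tolerance = 1e-6)
})

test_that("feature matrix has the stated geometry and interpolation rule", {
  m <- spikingMembrane()
  ampsFull <- c(-90, -50, -10, seq(40, 160, by = 20))
  cells <- list(full = makeCellSweeps(ampsFull, m),
                gappy = makeCellSweeps(setdiff(ampsFull, c(-50, 120)), m))
  fm <- buildFeatureMatrix(cells)
  expect_identical(fm@dropped, character())
  cat6 <- featureCategories(fm)
  # (e): 3 steps x 100 bins = 300; (d): 3 amplitudes x 50 bins
  expect_identical(sum(cat6 == "e"), 300L)
  expect_identical(sum(cat6 == "d"), 150L)
  vals <- featureValues(fm)
  # any spiking step: max normalized rate bin is 1
  for (cell in rownames(vals)) {
    d <- vals[cell, cat6 == "d"]
    expect_equal(max(d[1:50]), 1)
  }
  # (f) is min/baseline-normalized into [0, 1]
  f <- vals[, cat6 == "f"]
  expect_true(all(f >= 0 & f <= 1 + 1e-9))
  # construction is deterministic
  fm2 <- buildFeatureMatrix(cells)
  expect_identical(featureValues(fm), featureValues(fm2))
})

test_that("a missing middle amplitude is the mean of its neighbors' bins", {
  m <- spikingMembrane()
  # rheobase is 80 pA for this membrane (15 mV / 200 MOhm); provide 80 and
  # 160 but not 120, so the +40 block must be interpolated
  sweeps80 <- makeCellSweeps(c(-90, -50, -10, 80, 160), m)
  sweeps120 <- makeCellSweeps(c(-90, -50, -10, 80, 120, 160), m)
  fmGap <- buildFeatureMatrix(list(c = sweeps80))
  fmAll <- buildFeatureMatrix(list(c = sweeps120))
  cat6 <- featureCategories(fmGap)
  dGap <- featureValues(fmGap)[1, cat6 == "d"]
  dAll <- featureValues(fmAll)[1, featureCategories(fmAll) == "d"]
  # blocks: bins 1..50 = rheobase, 51..100 = +40, 101..150 = +80
  expect_equal(unname(dGap[1:50]), unname(dAll[1:50]))
  expect_equal(unname(dGap[101:150]), unname(dAll[101:150]))
  expect_equal(unname(dGap[51:100]),
               unname((dGap[1:50] + dGap[101:150]) / 2))
  # a cell with no spiking sweep is dropped with its id recorded
  none <- buildFeatureMatrix(list(dead = makeCellSweeps(c(-90, -10, 40), m)))
  expect_identical(none@dropped, "dead")
})

test_that("sparse PCA at zero penalty matches the dense eigendecomposition", {
  set.seed(3)
  x <- matrix(rnorm(60), 10, 6)
  fm <- new("FeatureMatrix", values = x, category = rep("a", 6),
            dropped = character())
  res <- suppressWarnings(sparsePCA(fm, penalty = 0, retention = 0))
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- ncol(res@loadings$a)
  for (j in seq_len(min(k, 4))) {
    expect_equal(abs(sum(res@loadings$a[, j] * pc$rotation[, j])), 1,
                 tolerance = 1e-6)
  }
  expect_equal(res@adjEV$a, pc$sdev^2 / sum(pc$sdev^2), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("adjusted explained variances are proper fractions and scores z-scored", {
  set.seed(9)
  x <- matrix(rnorm(400), 40, 10)
  fm <- new("FeatureMatrix", values = x,
            category = rep(c("a", "b"), each = 5), dropped = character())
  res <- sparsePCA(fm, penalty = 0.2)
  for (cat in names(res@adjEV)) {
    expect_true(all(res@adjEV[[cat]] >= 0))
    expect_lte(sum(res@adjEV[[cat]]), 1 + 1e-9)
  }
  sc <- spcaScores(res)
  expect_equal(colMeans(sc), rep(0, ncol(sc)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(apply(sc, 2, sd), rep(1, ncol(sc)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a planted dominant direction is retained and recovered", {
  set.seed(5)
  dir <- rnorm(8); dir <- dir / sqrt(sum(dir^2))
  scoresTrue <- rnorm(60, sd = 6)
  x <- outer(scoresTrue, dir) + matrix(rnorm(480, sd = 0.5), 60, 8)
  fm <- new("FeatureMatrix", values = x, category = rep("a", 8),
            dropped = character())
  res <- sparsePCA(fm, penalty = 0.1)
  expect_true(res@kept$a[1])
  cosine <- abs(sum(res@loadings$a[, 1] * dir))
  expect_gt(cosine, 0.95)
})
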