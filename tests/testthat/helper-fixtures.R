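# Shared fixtures, built in code and memoized per test run.

fixtureEnv <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = fixtureEnv)) {
    assign(key, builder(), envir = fixtureEnv)
  }
  get(key, envir = fixtureEnv)
}

# A small, well-separated reference taxonomy (3 classes x 2 types).
smallTax <- function() {
  memo("smallTax", function() {
    makeReference(synthConfig(seed = 11, nClasses = 3, typesPerClass = 2,
                              nGenes = 600, markersPerClass = 20,
                              markersPerType = 8, nRefCellsPerType = 15))
  })
}

smallMarkers <- function() {
  memo("smallMarkers", function() selectMarkers(smallTax(), nMarkers = 20))
}

smallFacs <- function() {
  memo("smallFacs", function() facsSummary(smallTax(), smallMarkers()))
}

# A regularly spiking membrane at 10 kHz for feature/ramp tests.
spikingMembrane <- function(samplingRate = 10) {
  tpl <- apTemplateWave(peakDvdt = 100, height = 60, ahp = 5,
                        samplingRate = samplingRate)
  membraneSpec(rmp = -70, rInput = 200, tau = 15, spikeThreshold = -55,
               apTemplate = tpl, samplingRate = samplingRate)
}

# Long-square sweep set over an amplitude grid for one cell.
makeCellSweeps <- function(amps, m = spikingMembrane(), seed = 1) {
  lapply(amps, function(a) {
    makeSweep(m, stimulusEpoch("long_square", 0.3, 1.3, a), seed = seed,
              duration = 1.8)
  })
}

# A flat trace with a piecewise-linear spike template pasted in.
traceWithTemplate <- function(peakDvdt, height = 60, at = 1000,
                              n = 3000, base = -70, samplingRate = 10) {
  v <- rep(base, n)
  tpl <- apTemplateWave(peakDvdt = peakDvdt, height = height,
                        samplingRate = samplingRate)
  v[at + seq_along(tpl) - 1L] <- base + tpl
  list(voltage = v, dt = 1 / (samplingRate * 1000))
}

# Constant-voltage sweep with one epoch, for baseline/recovery tests.
flatSweep <- function(level, duration = 1.2, dt = 2e-4,
                      epochs = stimulusEpoch("long_square", 0.6, 0.7, 0)) {
  n <- round(duration / dt)
  new("VoltageSweep", startTime = 0, dt = dt,
      voltage = rep(level, n), stimulus = numeric(n), epochs = epochs)
}

# Brute-force AUC by concordant-pair counting (ties count half).
pairCountAuc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# A tiny hand-built taxonomy with exactly controllable profiles.
handTax <- function() {
  memo("handTax", function() {
    genes <- sprintf("g%02d", 1:8)
    # class A markers g1,g2; class B markers g3,g4; type markers g5..g8
    prof <- cbind(
      A_t1 = c(5, 5, 0, 0, 4, 0, 0, 0),
      A_t2 = c(5, 5, 0, 0, 0, 4, 0, 0),
      B_t1 = c(0, 0, 5, 5, 0, 0, 4, 0),
      B_t2 = c(0, 0, 5, 5, 0, 0, 0, 4))
    rownames(prof) <- genes
    # 3 reference cells per type, small deterministic perturbations
    cellType <- rep(colnames(prof), each = 3)
    exprs <- prof[, cellType]
    set.seed(42)
    exprs <- exprs +
      matrix(runif(length(exprs), 0, 0.01), nrow(exprs)) * (exprs > 0)
    colnames(exprs) <- sprintf("hc%02d", seq_len(ncol(exprs)))
    new("ReferenceTaxonomy",
        exprs = exprs, cellType = cellType,
        classOf = c(A_t1 = "A", A_t2 = "A", B_t1 = "B", B_t2 = "B"),
        children = list(root = c("A", "B"), A = c("A_t1", "A_t2"),
                        B = c("B_t1", "B_t2")),
        branchMarkers = list(root = genes[1:4], A = genes[5:6],
                             B = genes[7:8]),
        typeMeans = prof,
        isGlia = c(A = FALSE, B = FALSE),
        plantedMarkers = list())
  })
}
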