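test_that("deterministic descent maps cluster means to their own leaves", {
  tax <- smallTax()
  for (lf in leafTypes(tax)) {
    expect_identical(mapCellOnce(tax@typeMeans[, lf], tax), lf)
  }
})

test_that("correlation ties resolve to the first declared child", {
  tax <- handTax()
  # equal correlation with both classes by symmetry of the marker blocks
  expr <- stats::setNames(c(1, 1, 1, 1, 4, 0, 4, 0), rownames(tax@exprs))
  # strip the perturbations so the tie is exact
  tax@exprs <- tax@typeMeans[, tax@cellType]
  colnames(tax@exprs) <- sprintf("hc%02d", seq_len(ncol(tax@exprs)))
  expect_identical(mapCellOnce(expr, tax), "A_t1")
  # descent path length equals tree depth: result is always a leaf
  expect_true(mapCellOnce(expr, tax) %in% leafTypes(tax))
})

test_that("bootstrap probabilities are 1/n_boot multiples, seeded and concentrated", {
  tax <- smallTax()
  lf <- leafTypes(tax)[3]
  res <- bootstrapMap(tax@typeMeans[, lf], tax, nBoot = 40, seed = 7)
  p <- mappingProbabilities(res)
  expect_equal(sum(p), 1)
  expect_true(all(abs(p * 40 - round(p * 40)) < 1e-9))
  # same seed twice: identical vector
  res2 <- bootstrapMap(tax@typeMeans[, lf], tax, nBoot = 40, seed = 7)
  expect_identical(p, mappingProbabilities(res2))
  # a noise-free cluster mean far from other types maps with probability 1
  expect_equal(unname(p[lf]), 1)
  # with full subsamples and no ties, all mass sits on the deterministic map
  resFull <- bootstrapMap(tax@typeMeans[, lf], tax, nBoot = 10, cellFrac = 1,
                          markerFrac = 1, seed = 1)
  expect_equal(unname(mappingProbabilities(resFull)[mapCellOnce(
    tax@typeMeans[, lf], tax)]), 1)
  expect_error(bootstrapMap(tax@typeMeans[, lf], tax, cellFrac = 0),
               "fractions")
})

test_that("the reference probability matrix is near-identity for separated types", {
  tax <- smallTax()
  refmat <- referenceProbabilityMatrix(tax, nBoot = 15, seed = 3)
  expect_equal(unname(rowSums(refmat)), rep(1, nrow(refmat)))
  expect_gt(min(diag(refmat)), 0.9)
})

test_that("KL divergence is smoothed, non-negative and asymmetric", {
  expect_equal(klDivergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(klDivergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-4)
  p <- c(0.9, 0.1); q <- c(0.5, 0.5)
  expect_false(isTRUE(all.equal(klDivergence(p, q), klDivergence(q, p))))
  set.seed(2)
  for (i in 1:20) {
    a <- runif(5); a <- a / sum(a)
    b <- runif(5); b <- b / sum(b)
    expect_gte(klDivergence(a, b), 0)
  }
  expect_error(klDivergence(c(1, 0), c(1, 0, 0)), "length")
})

test_that("consistency rules fire in their stated order", {
  tax <- smallTax()
  leaves <- leafTypes(tax)
  lf <- leaves[1]
  expr <- tax@typeMeans[, lf]
  refmat <- diag(length(leaves))
  dimnames(refmat) <- list(leaves, leaves)

  mkProb <- function(p) {
    stats::setNames(c(p, rep((1 - sum(p)) / (length(leaves) - length(p)),
                             length(leaves) - length(p))), leaves)
  }
  # KL beyond 2 forces inconsistent even with perfect correlation
  awayRef <- refmat
  awayRef[lf, ] <- mkProb(c(0.01))
  resKL <- classifyConsistency(mappingResult(mkProb(0.9)), awayRef, expr, tax)
  expect_gt(resKL@kl, 2)
  expect_identical(mappingConsistency(resKL), "inconsistent")
  # (0.6, 0.2, 0.2, ...): top-two sum 0.8 > 0.7 and ratio 3 > 2: highly
  okRef <- refmat
  okRef[lf, ] <- mkProb(c(0.6, 0.2, 0.2))
  resHi <- classifyConsistency(mappingResult(mkProb(c(0.6, 0.2, 0.2))),
                               okRef, expr, tax)
  expect_identical(mappingConsistency(resHi), "highly")
  # (0.40, 0.35, 0.25): ratio 1.14 <= 2: moderately
  modRef <- refmat
  modRef[lf, ] <- mkProb(c(0.40, 0.35, 0.25))
  resMod <- classifyConsistency(mappingResult(mkProb(c(0.40, 0.35, 0.25))),
                                modRef, expr, tax)
  expect_identical(mappingConsistency(resMod), "moderately")
  # low expression correlation forces inconsistent despite clean mapping
  fullRef <- refmat
  fullRef[lf, ] <- mkProb(1 - 1e-9)
  flat <- stats::setNames(rep(1, nrow(tax@exprs)), rownames(tax@exprs))
  resCor <- classifyConsistency(mappingResult(mkProb(1 - 1e-9)), fullRef,
                                flat, tax)
  expect_lt(resCor@typeCorrelation, 0.5)
  expect_identical(mappingConsistency(resCor), "inconsistent")
  # unknown assigned type errors
  badRef <- refmat[-1, ]
  expect_error(classifyConsistency(mappingResult(mkProb(0.9)), badRef,
                                   expr, tax), "missing")
})

test_that("consistency labels are invariant to leaf-order permutation", {
  tax <- smallTax()
  leaves <- leafTypes(tax)
  expr <- tax@typeMeans[, leaves[2]]
  p <- stats::setNames(c(0.1, 0.62, 0.18, 0.1, 0, 0), leaves)
  refmat <- diag(length(leaves)) * 0.9 + 0.02
  dimnames(refmat) <- list(leaves, leaves)
  refmat <- refmat / rowSums(refmat)
  lab <- mappingConsistency(
    classifyConsistency(mappingResult(p), refmat, expr, tax))
  perm <- rev(leaves)
  lab2 <- mappingConsistency(
    classifyConsistency(mappingResult(p[perm]), refmat[perm, perm], expr,
                        tax))
  expect_identical(lab, lab2)
})

test_that("mapCells joins mapping and consistency per cell", {
  tax <- smallTax()
  out <- makePatchseqCells(tax, cellSimSpec(leafTypes(tax)[c(1, 4)]),
                           seed = 8, noiseSd = 0.05)
  df <- mapCells(out$exprs, tax, nBoot = 12, seed = 5)
  expect_identical(df$assignedType, leafTypes(tax)[c(1, 4)])
  expect_true(all(df$consistency %in%
                    c("highly", "moderately", "inconsistent")))
  expect_identical(df$cellId, colnames(out$exprs))
})
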