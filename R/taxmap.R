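#' Deterministic top-down mapping of one cell
#'
#' Descends the taxonomy from the root: at each internal node the Pearson
#' correlation between the cell and each child's cluster mean profile is
#' computed over that node's branch markers (restricted to
#' \code{markerSubset}, with cluster means recomputed on \code{cellSubset});
#' the most-correlated child is chosen, ties broken by declared child order,
#' until a leaf is reached.
#'
#' @param expr named numeric, the cell's log2(CPM+1) profile covering the
#'   branch markers.
#' @param tax A [ReferenceTaxonomy-class].
#' @param cellSubset reference cell indices (or names) to use; NULL = all.
#' @param markerFrac if < 1, the fraction of each node's markers resampled
#'   (uses the current RNG stream); 1 = all markers.
#' @return leaf type id (character).
#' @export
mapCellOnce <- function(expr, tax, cellSubset = NULL, markerFrac = 1) {
  cells <- seq_len(ncol(tax@exprs))
  if (!is.null(cellSubset)) cells <- cellSubset
  cellLeaf <- tax@cellType
  node <- "root"
  while (node %in% names(tax@children)) {
    markers <- tax@branchMarkers[[node]]
    if (markerFrac < 1) {
      nKeep <- max(1L, round(markerFrac * length(markers)))
      markers <- markers[sort(sample.int(length(markers), nKeep))]
    }
    if (!length(markers)) stop("empty marker set at node ", node)
    kids <- tax@children[[node]]
    x <- expr[markers]
    best <- -Inf
    pick <- kids[1]
    for (ch in kids) {
      under <- leavesUnder(tax, ch)
      members <- cells[cellLeaf[cells] %in% under]
      if (!length(members)) stop("subset emptied node ", ch)
      prof <- rowMeans(tax@exprs[markers, members, drop = FALSE])
      r <- suppressWarnings(stats::cor(x, prof))
      if (is.na(r)) r <- -Inf
      if (r > best + 1e-15) {
        best <- r
        pick <- ch
      }
    }
    node <- pick
  }
  node
}

#' Bootstrapped taxonomy mapping of one cell
#'
#' Runs \code{nBoot} independent top-down descents; in each, a fraction
#' \code{cellFrac} of the reference cells is resampled within every leaf type
#' (stratified, so no cluster empties) and a fraction \code{markerFrac} of
#' the markers is resampled at every branch point. The mapping probability of
#' a leaf is the fraction of descents ending there; the assigned type is the
#' argmax. Deterministic given the seed.
#'
#' @param expr named numeric cell profile.
#' @param tax A [ReferenceTaxonomy-class].
#' @param nBoot bootstrap iterations (default 100).
#' @param cellFrac fraction of reference cells per leaf per descent.
#' @param markerFrac fraction of markers per branch point per descent.
#' @param seed integer.
#' @return A [MappingResult-class] (probabilities and assignment;
#'   consistency fields are filled by [classifyConsistency()]).
#' @export
bootstrapMap <- function(expr, tax, nBoot = 100L, cellFrac = 0.7,
                         markerFrac = 0.7, seed = 1L) {
  if (cellFrac <= 0 || cellFrac > 1 || markerFrac <= 0 || markerFrac > 1) {
    stop("fractions must be in (0, 1]")
  }
  leaves <- leafTypes(tax)
  byLeaf <- lapply(leaves, function(lf) which(tax@cellType == lf))
  names(byLeaf) <- leaves
  hits <- integer(length(leaves))
  names(hits) <- leaves
  for (b in seq_len(nBoot)) {
    leaf <- withSeed(childSeed(seed, b), {
      cellSubset <- if (cellFrac < 1) {
        unlist(lapply(byLeaf, function(idx) {
          idx[sample.int(length(idx), max(1L, round(cellFrac * length(idx))))]
        }), use.names = FALSE)
      } else NULL
      mapCellOnce(expr, tax, cellSubset, markerFrac)
    })
    hits[leaf] <- hits[leaf] + 1L
  }
  p <- hits / nBoot
  new("MappingResult", probabilities = p,
      assignedType = names(p)[which.max(p)], nBoot = as.integer(nBoot),
      kl = NA_real_, typeCorrelation = NA_real_,
      consistency = NA_character_)
}

#' Reference mapping probability matrix
#'
#' Bootstrap-maps every reference cell onto its own taxonomy and averages the
#' probability vectors within each leaf type. Rows (types) sum to 1; on a
#' well-separated taxonomy the matrix is close to the identity, and its
#' off-diagonal mass records the expected, biological mapping ambiguity that
#' the consistency classification discounts.
#'
#' @param tax A [ReferenceTaxonomy-class].
#' @inheritParams bootstrapMap
#' @return numeric matrix, leaf types x leaf types.
#' @export
referenceProbabilityMatrix <- function(tax, nBoot = 100L, cellFrac = 0.7,
                                       markerFrac = 0.7, seed = 1L) {
  leaves <- leafTypes(tax)
  probs <- matrix(0, ncol(tax@exprs), length(leaves),
                  dimnames = list(colnames(tax@exprs), leaves))
  for (i in seq_len(ncol(tax@exprs))) {
    res <- bootstrapMap(tax@exprs[, i], tax, nBoot, cellFrac, markerFrac,
                        seed = childSeed(seed, 100000 + i))
    probs[i, ] <- res@probabilities[leaves]
  }
  refmat <- vapply(leaves, function(lf) {
    colMeans(probs[tax@cellType == lf, , drop = FALSE])
  }, numeric(length(leaves)))
  t(refmat)
}

#' Kullback-Leibler divergence between probability vectors
#'
#' Both vectors are floored at \code{epsilon} and renormalized before
#' computing \code{sum(p * log(p / q))} in nats, so zero probabilities are
#' handled smoothly. Non-negative; zero only for identical smoothed
#' distributions; asymmetric in its arguments.
#'
#' @param p,q non-negative vectors of equal length.
#' @param epsilon smoothing floor.
#' @return numeric, nats.
#' @examples
#' klDivergence(c(1, 0), c(0.5, 0.5))  # ~ log(2)
#' @export
klDivergence <- function(p, q, epsilon = 1e-6) {
  if (length(p) != length(q)) stop("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) stop("probabilities must be >= 0")
  p <- pmax(p, epsilon); p <- p / sum(p)
  q <- pmax(q, epsilon); q <- q / sum(q)
  sum(p * log(p / q))
}

#' Default mapping-consistency thresholds
#'
#' @param klMax KL divergence above which a cell is inconsistent (strict).
#' @param corMin expression correlation below which a cell is inconsistent
#'   (strict).
#' @param topSum top-two probability sum that must be exceeded (strict).
#' @param topRatio top1/top2 probability ratio that must be exceeded
#'   (strict); a zero second probability counts as infinite ratio.
#' @return named list.
#' @export
consistencyThresholds <- function(klMax = 2, corMin = 0.5, topSum = 0.7,
                                  topRatio = 2) {
  list(klMax = klMax, corMin = corMin, topSum = topSum, topRatio = topRatio)
}

#' Classify mapping consistency
#'
#' Rules applied in order: (1) if the KL divergence between the cell's
#' bootstrap probabilities and the assigned type's row of the reference
#' probability matrix exceeds \code{klMax}, the cell is inconsistent; (2) if
#' the Pearson correlation between the cell's expression and the assigned
#' type's mean profile (over the union of branch markers along the assigned
#' root-to-leaf path) is below \code{corMin}, the cell is inconsistent;
#' (3) if the sum of the two highest probabilities exceeds \code{topSum} and
#' the top1/top2 ratio exceeds \code{topRatio}, the cell is highly
#' consistent; (4) otherwise moderately consistent.
#'
#' @param result A [MappingResult-class] from [bootstrapMap()].
#' @param refmat matrix from [referenceProbabilityMatrix()].
#' @param expr the cell's expression profile (named, log2(CPM+1)).
#' @param tax A [ReferenceTaxonomy-class].
#' @param thresholds from [consistencyThresholds()].
#' @return the [MappingResult-class] with \code{kl},
#'   \code{typeCorrelation} and \code{consistency} filled in.
#' @export
classifyConsistency <- function(result, refmat, expr, tax,
                                thresholds = consistencyThresholds()) {
  assigned <- result@assignedType
  if (!assigned %in% rownames(refmat)) {
    stop("assigned type ", assigned, " missing from the reference matrix")
  }
  leaves <- colnames(refmat)
  kl <- klDivergence(result@probabilities[leaves], refmat[assigned, leaves])
  markers <- pathMarkers(tax, assigned)
  prof <- rowMeans(tax@exprs[markers, tax@cellType == assigned,
                             drop = FALSE])
  corr <- suppressWarnings(stats::cor(expr[markers], prof))
  if (is.na(corr)) corr <- -1
  p <- sort(result@probabilities, decreasing = TRUE)
  ratio <- if (length(p) < 2L || p[2] == 0) Inf else p[1] / p[2]
  topSum <- if (length(p) >= 2L) p[1] + p[2] else p[1]
  label <- if (kl > thresholds$klMax) {
    "inconsistent"
  } else if (corr < thresholds$corMin) {
    "inconsistent"
  } else if (topSum > thresholds$topSum && ratio > thresholds$topRatio) {
    "highly"
  } else {
    "moderately"
  }
  initialize(result, kl = kl, typeCorrelation = corr, consistency = label)
}

# Union of branch markers along the root-to-leaf path.
pathMarkers <- function(tax, leaf) {
  parentOf <- stats::setNames(
    rep(names(tax@children), lengths(tax@children)),
    unlist(tax@children, use.names = FALSE))
  markers <- character()
  node <- leaf
  while (node %in% names(parentOf)) {
    node <- parentOf[[node]]
    markers <- c(markers, tax@branchMarkers[[node]])
  }
  unique(markers)
}

#' Construct a mapping result from explicit probabilities
#'
#' Mainly for boundary analyses of the consistency rules: wraps a probability
#' vector (with leaf-type names) into a [MappingResult-class].
#'
#' @param probabilities named non-negative vector summing to 1.
#' @param nBoot granularity; 0L skips the multiple-of-1/nBoot check.
#' @return A [MappingResult-class].
#' @export
mappingResult <- function(probabilities, nBoot = 0L) {
  new("MappingResult", probabilities = probabilities,
      assignedType = names(probabilities)[which.max(probabilities)],
      nBoot = as.integer(nBoot), kl = NA_real_,
      typeCorrelation = NA_real_, consistency = NA_character_)
}

#' Map and classify a set of cells
#'
#' Convenience pipeline: bootstrap-maps every column of \code{exprs} and
#' classifies its consistency against the reference probability matrix.
#'
#' @param exprs genes x cells matrix, log2(CPM+1).
#' @param tax A [ReferenceTaxonomy-class].
#' @param refmat from [referenceProbabilityMatrix()] (computed if NULL).
#' @inheritParams bootstrapMap
#' @param thresholds from [consistencyThresholds()].
#' @return data.frame: cellId, assignedType, topProbability, kl,
#'   typeCorrelation, consistency, plus one probability column per leaf.
#' @export
mapCells <- function(exprs, tax, refmat = NULL, nBoot = 100L, cellFrac = 0.7,
                     markerFrac = 0.7, seed = 1L,
                     thresholds = consistencyThresholds()) {
  if (is.null(refmat)) {
    refmat <- referenceProbabilityMatrix(tax, nBoot, cellFrac, markerFrac,
                                         seed = childSeed(seed, 1))
  }
  leaves <- leafTypes(tax)
  rows <- lapply(seq_len(ncol(exprs)), function(j) {
    res <- bootstrapMap(exprs[, j], tax, nBoot, cellFrac, markerFrac,
                        seed = childSeed(seed, 1000 + j))
    res <- classifyConsistency(res, refmat, exprs[, j], tax, thresholds)
    cbind(data.frame(cellId = colnames(exprs)[j],
                     assignedType = res@assignedType,
                     topProbability = max(res@probabilities),
                     kl = res@kl, typeCorrelation = res@typeCorrelation,
                     consistency = res@consistency,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(res@probabilities[leaves])))
  })
  do.call(rbind, rows)
}
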