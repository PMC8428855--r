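#' Create a synthetic-reference configuration
#'
#' The defaults define a compact but realistic desk-scale analogue of a
#' dissociated-cell cortical reference: a few neuronal classes plus one glial
#' class, each class split into leaf types, with disjoint planted marker
#' blocks whose in-class elevation (in log2 units) makes them recoverable by
#' differential-expression ranking.
#'
#' @param seed integer master seed.
#' @param nClasses number of broad classes (>= 2 recommended).
#' @param typesPerClass leaf types per class.
#' @param nGenes total genes.
#' @param markersPerClass planted class markers per class.
#' @param markersPerType planted type markers per leaf type.
#' @param markerEffect log2 units added to class-marker means in class.
#' @param typeEffect log2 units added to type-marker means in type.
#' @param nRefCellsPerType reference cells per leaf type.
#' @param noiseSd per-cell log2 noise SD.
#' @param gliaClasses how many classes are non-neuronal (contamination
#'   sources); the last \code{gliaClasses} classes are glial.
#' @param nbSize negative-binomial size for count draws.
#' @param libSize expected total counts per cell.
#' @return A [SynthConfig-class] object.
#' @examples
#' cfg <- synthConfig(seed = 1, nClasses = 3, typesPerClass = 2)
#' @export
synthConfig <- function(seed = 1L, nClasses = 4L, typesPerClass = 2L,
                        nGenes = 1000L, markersPerClass = 50L,
                        markersPerType = 10L, markerEffect = 4,
                        typeEffect = 4, nRefCellsPerType = 30L,
                        noiseSd = 0.3, gliaClasses = 1L, nbSize = 20,
                        libSize = 5e5) {
  new("SynthConfig",
      seed = as.integer(seed), nClasses = as.integer(nClasses),
      typesPerClass = as.integer(typesPerClass), nGenes = as.integer(nGenes),
      markersPerClass = as.integer(markersPerClass),
      markersPerType = as.integer(markersPerType),
      markerEffect = markerEffect, typeEffect = typeEffect,
      nRefCellsPerType = as.integer(nRefCellsPerType), noiseSd = noiseSd,
      gliaClasses = as.integer(gliaClasses), nbSize = nbSize,
      libSize = libSize)
}

#' Generate a synthetic reference taxonomy
#'
#' Builds a root -> class -> leaf-type hierarchy and simulates reference
#' cells. Gene mean profiles are defined in log2 space: marker genes sit on a
#' low common baseline and are elevated by \code{markerEffect} (class markers,
#' in every type of their class) or \code{typeEffect} (type markers, in their
#' own type only); non-marker genes share a gene-specific baseline. Counts are
#' drawn negative-binomially around each cell's (log-normally jittered) mean
#' profile, CPM-normalized and log2(x+1)-transformed. Per-type cluster means
#' are the mean linear CPM profiles, re-normalized to 1e6 and stored in
#' log2(CPM+1) space. Generation is a pure function of \code{cfg@seed}.
#'
#' @param cfg A [SynthConfig-class].
#' @return A [ReferenceTaxonomy-class].
#' @examples
#' tax <- makeReference(synthConfig(seed = 7, nClasses = 3))
#' @export
makeReference <- function(cfg) {
  validObject(cfg)
  withSeed(cfg@seed, {
    nC <- cfg@nClasses; nT <- cfg@typesPerClass; nG <- cfg@nGenes
    nGlia <- cfg@gliaClasses
    genes <- sprintf("g%04d", seq_len(nG))
    classes <- c(
      if (nC - nGlia > 0) sprintf("N%d", seq_len(nC - nGlia)),
      if (nGlia > 0) sprintf("G%d", seq_len(nGlia))
    )
    isGlia <- stats::setNames(grepl("^G", classes), classes)
    leaves <- unlist(lapply(classes, function(cl) {
      sprintf("%s_t%d", cl, seq_len(nT))
    }))
    classOf <- stats::setNames(rep(classes, each = nT), leaves)

    # disjoint marker blocks, class blocks first then type blocks
    cursor <- 0L
    takeBlock <- function(n) {
      idx <- genes[cursor + seq_len(n)]
      cursor <<- cursor + n
      idx
    }
    classMarkers <- stats::setNames(
      lapply(classes, function(cl) takeBlock(cfg@markersPerClass)), classes)
    typeMarkers <- stats::setNames(
      lapply(leaves, function(lf) takeBlock(cfg@markersPerType)), leaves)

    # baseline log2 mean (relative abundance): housekeeping genes spread over
    # a broad expressed range; marker genes sit near the dropout floor so
    # they are mostly undetected outside their own block, as real class
    # markers are
    baseLog2 <- stats::runif(nG, 2, 6)
    names(baseLog2) <- genes
    markerGenes <- c(unlist(classMarkers), unlist(typeMarkers))
    baseLog2[markerGenes] <- -7

    typeLog2 <- matrix(baseLog2, nrow = nG, ncol = length(leaves),
                       dimnames = list(genes, leaves))
    for (lf in leaves) {
      cl <- classOf[[lf]]
      typeLog2[classMarkers[[cl]], lf] <-
        typeLog2[classMarkers[[cl]], lf] + cfg@markerEffect
      typeLog2[typeMarkers[[lf]], lf] <-
        typeLog2[typeMarkers[[lf]], lf] + cfg@typeEffect
    }

    nCells <- length(leaves) * cfg@nRefCellsPerType
    cellType <- rep(leaves, each = cfg@nRefCellsPerType)
    cellIds <- sprintf("ref%04d", seq_len(nCells))
    counts <- matrix(0, nrow = nG, ncol = nCells,
                     dimnames = list(genes, cellIds))
    for (j in seq_len(nCells)) {
      lmu <- typeLog2[, cellType[j]]
      if (cfg@noiseSd > 0) lmu <- lmu + stats::rnorm(nG, 0, cfg@noiseSd)
      mu <- 2^lmu
      mu <- mu / sum(mu) * cfg@libSize
      counts[, j] <- stats::rnbinom(nG, mu = mu, size = cfg@nbSize)
    }
    exprs <- log2cpm(counts)

    # per-type cluster means: mean linear CPM, re-normalized to 1e6
    cpm <- 2^exprs - 1
    typeMeans <- vapply(leaves, function(lf) {
      m <- rowMeans(cpm[, cellType == lf, drop = FALSE])
      log2(m / sum(m) * 1e6 + 1)
    }, numeric(nG))
    dimnames(typeMeans) <- list(genes, leaves)

    children <- c(list(root = classes),
                  stats::setNames(lapply(classes, function(cl) {
                    leaves[classOf == cl]
                  }), classes))
    branchMarkers <- c(
      list(root = unname(unlist(classMarkers))),
      stats::setNames(lapply(classes, function(cl) {
        unname(unlist(typeMarkers[leaves[classOf == cl]]))
      }), classes))

    new("ReferenceTaxonomy",
        exprs = exprs, cellType = cellType, classOf = classOf,
        children = children, branchMarkers = branchMarkers,
        typeMeans = typeMeans, isGlia = isGlia,
        plantedMarkers = list(class = classMarkers, type = typeMarkers))
  })
}

#' @describeIn ReferenceTaxonomy-class leaf-type ids (tree leaves).
#' @param tax A \code{ReferenceTaxonomy}.
#' @export
leafTypes <- function(tax) {
  setdiff(unlist(tax@children, use.names = FALSE), names(tax@children))
}

#' @describeIn ReferenceTaxonomy-class the log2(CPM+1) reference matrix.
#' @export
refExprs <- function(tax) tax@exprs

#' @describeIn ReferenceTaxonomy-class per-type cluster mean profiles.
#' @export
typeMeans <- function(tax) tax@typeMeans

#' @describeIn ReferenceTaxonomy-class per-cell leaf-type labels.
#' @export
refCellTypes <- function(tax) stats::setNames(tax@cellType,
                                              colnames(tax@exprs))

#' @describeIn ReferenceTaxonomy-class leaves under an internal node.
#' @param node internal node id.
#' @export
leavesUnder <- function(tax, node) {
  kids <- tax@children
  if (!node %in% names(kids)) return(node)
  unlist(lapply(kids[[node]], leavesUnder, tax = tax), use.names = FALSE)
}
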