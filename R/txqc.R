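#' Select class marker genes from a reference taxonomy
#'
#' For each class, genes are ranked by the differential score
#' (mean in class - max mean over other classes) x (detection fraction in
#' class - max detection fraction elsewhere), computed in log2(CPM+1) space
#' with detection defined as expression > 0. Each gene can serve at most one
#' class (the class where it scores highest); ties are broken
#' lexicographically by gene name. The top \code{nMarkers} owned genes per
#' class become that class's on-markers. By default every other class is
#' counted as "off" when scoring contamination; pass \code{offClasses} to
#' restrict (e.g. non-neuronal subclasses plus the opposite neuronal class).
#'
#' @param tax A [ReferenceTaxonomy-class].
#' @param nMarkers markers per class (default 50).
#' @param offClasses optional named list class -> off classes.
#' @return A [MarkerSets-class].
#' @export
selectMarkers <- function(tax, nMarkers = 50L, offClasses = NULL) {
  classes <- names(tax@isGlia)
  if (nMarkers > nrow(tax@exprs)) {
    stop("nMarkers exceeds the number of genes")
  }
  cellClass <- tax@classOf[tax@cellType]
  means <- vapply(classes, function(cl) {
    rowMeans(tax@exprs[, cellClass == cl, drop = FALSE])
  }, numeric(nrow(tax@exprs)))
  det <- vapply(classes, function(cl) {
    rowMeans(tax@exprs[, cellClass == cl, drop = FALSE] > 0)
  }, numeric(nrow(tax@exprs)))
  score <- matrix(0, nrow(tax@exprs), length(classes),
                  dimnames = list(rownames(tax@exprs), classes))
  for (j in seq_along(classes)) {
    otherM <- apply(means[, -j, drop = FALSE], 1, max)
    otherD <- apply(det[, -j, drop = FALSE], 1, max)
    dm <- means[, j] - otherM
    dd <- det[, j] - otherD
    s <- dm * dd
    # a gene depleted in both mean and detection is an anti-marker, not a
    # marker: its two negative factors must not yield a positive score
    s[dm <= 0 | dd <= 0] <- 0
    score[, j] <- s
  }
  owner <- classes[max.col(score, ties.method = "first")]
  onMarkers <- stats::setNames(lapply(classes, function(cl) {
    mine <- which(owner == cl & score[, cl] > 0)
    if (length(mine) < nMarkers) {
      stop("class ", cl, " has only ", length(mine),
           " genes with positive differential signal; need ", nMarkers)
    }
    g <- rownames(score)[mine]
    g[order(-score[mine, cl], g)][seq_len(nMarkers)]
  }), classes)
  if (is.null(offClasses)) {
    offClasses <- stats::setNames(lapply(classes, function(cl) {
      setdiff(classes, cl)
    }), classes)
  }
  new("MarkerSets", onMarkers = onMarkers, offClasses = offClasses)
}

#' Summarize the reference (FACS) data for marker scoring
#'
#' Per class: the median, over that class's reference cells, of the mean
#' on-marker log2(CPM+1) expression (the denominator of the normalized marker
#' sum; the median of per-cell means resolves the wording ambiguity and makes
#' the within-class median norm exactly 1). Per leaf type: the mean
#' expression profile over the union of all on-markers (used for the quality
#' score).
#'
#' @param tax A [ReferenceTaxonomy-class].
#' @param markers A [MarkerSets-class].
#' @return A [FacsSummary-class].
#' @export
facsSummary <- function(tax, markers) {
  cellClass <- tax@classOf[tax@cellType]
  classes <- names(markers@onMarkers)
  classMedians <- vapply(classes, function(cl) {
    cells <- cellClass == cl
    stats::median(colMeans(
      tax@exprs[markers@onMarkers[[cl]], cells, drop = FALSE]))
  }, numeric(1))
  union <- unique(unlist(markers@onMarkers, use.names = FALSE))
  leaves <- leafTypes(tax)
  typeProfiles <- vapply(leaves, function(lf) {
    rowMeans(tax@exprs[union, tax@cellType == lf, drop = FALSE])
  }, numeric(length(union)))
  dimnames(typeProfiles) <- list(union, leaves)
  new("FacsSummary", classMedians = classMedians,
      typeProfiles = typeProfiles,
      typeClass = tax@classOf[leaves])
}

#' Transcriptomic quality scores for one or more cells
#'
#' For each class \code{c} the per-class norm is the cell's mean on-marker
#' expression divided by the class's FACS median. The normalized marker sum
#' (NMS) is the maximum norm, the assigned class its argmax; the
#' contamination score is the sum of norms over the assigned class's off
#' classes (no clipping); and the quality score is the Spearman correlation
#' between the cell's on-marker-union vector and the mean profile of the
#' best-matching leaf type within the assigned class. Classes whose FACS
#' median is zero are excluded with a warning. A cell passes iff
#' \code{NMS >= cutoff}.
#'
#' @param exprs numeric vector (one cell) or genes x cells matrix in
#'   log2(CPM+1) space, covering all marker genes by name.
#' @param markers A [MarkerSets-class].
#' @param facs A [FacsSummary-class].
#' @param cutoff NMS pass cutoff (default 0.4, boundary inclusive).
#' @return data.frame with one row per cell: \code{nms},
#'   \code{assignedClass}, \code{contamination}, \code{qualityScore},
#'   \code{passed}.
#' @export
scoreCells <- function(exprs, markers, facs, cutoff = 0.4) {
  if (is.null(dim(exprs))) {
    exprs <- matrix(exprs, ncol = 1,
                    dimnames = list(names(exprs), "cell1"))
  }
  med <- facs@classMedians
  usable <- med > 0
  if (any(!usable)) {
    warning("excluding class(es) with zero FACS median: ",
            paste(names(med)[!usable], collapse = ", "))
  }
  classes <- names(med)[usable]
  missing <- setdiff(unlist(markers@onMarkers[classes]), rownames(exprs))
  if (length(missing)) {
    stop("expression input lacks marker gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  norms <- vapply(classes, function(cl) {
    colMeans(exprs[markers@onMarkers[[cl]], , drop = FALSE]) / med[[cl]]
  }, numeric(ncol(exprs)))
  if (ncol(exprs) == 1L) norms <- matrix(norms, nrow = 1,
                                         dimnames = list(NULL, classes))
  union <- rownames(facs@typeProfiles)
  out <- data.frame(
    cellId = colnames(exprs), nms = NA_real_, assignedClass = NA_character_,
    contamination = NA_real_, qualityScore = NA_real_, passed = NA,
    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(exprs))) {
    nj <- norms[j, ]
    best <- which.max(nj)
    cl <- classes[best]
    off <- intersect(markers@offClasses[[cl]], classes)
    types <- names(facs@typeClass)[facs@typeClass == cl]
    cellVec <- exprs[union, j]
    qs <- suppressWarnings(max(vapply(types, function(tp) {
      stats::cor(cellVec, facs@typeProfiles[, tp], method = "spearman")
    }, numeric(1)), na.rm = TRUE))
    if (!is.finite(qs)) qs <- NA_real_
    out$nms[j] <- nj[[best]]
    out$assignedClass[j] <- cl
    out$contamination[j] <- sum(nj[off])
    out$qualityScore[j] <- qs
    out$passed[j] <- classifyQuality(nj[[best]], cutoff)
  }
  out
}

#' NMS pass/fail classification
#'
#' A cell passes transcriptomic QC iff its normalized marker sum is at least
#' the cutoff; the boundary value itself passes.
#'
#' @param nms numeric NMS value(s).
#' @param cutoff default 0.4.
#' @return logical.
#' @examples
#' classifyQuality(c(0.39, 0.4, 1.2))  # FALSE TRUE TRUE
#' @export
classifyQuality <- function(nms, cutoff = 0.4) {
  nms >= cutoff
}
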