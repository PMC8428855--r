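#' Specify simulated Patch-seq cells
#'
#' Builds the per-cell simulation table consumed by [makePatchseqCells()].
#' \code{qualityFactor} scales the whole captured mRNA content (1 = the full
#' type profile, 0 = nothing detected); \code{contaminationFraction} mixes in
#' the glial mean profile, emulating off-target mRNA picked up as the pipette
#' travels through tissue.
#'
#' @param trueType character, leaf-type id per cell.
#' @param nucleusPlus logical, nucleus extracted per cell.
#' @param qualityFactor numeric in [0, 1].
#' @param contaminationFraction numeric in [0, 1).
#' @return data.frame with one row per cell.
#' @export
cellSimSpec <- function(trueType, nucleusPlus = TRUE, qualityFactor = 1,
                        contaminationFraction = 0) {
  df <- data.frame(
    trueType = trueType, nucleusPlus = nucleusPlus,
    qualityFactor = qualityFactor,
    contaminationFraction = contaminationFraction,
    stringsAsFactors = FALSE
  )
  if (any(df$qualityFactor < 0 | df$qualityFactor > 1)) {
    stop("qualityFactor must be in [0, 1]")
  }
  if (any(df$contaminationFraction < 0 | df$contaminationFraction >= 1)) {
    stop("contaminationFraction must be in [0, 1)")
  }
  df
}

#' Simulate Patch-seq expression profiles
#'
#' Each cell's linear CPM profile is
#' \code{qualityFactor * typeCPM + contaminationFraction * gliaCPM}, where
#' \code{typeCPM} is the true type's cluster mean and \code{gliaCPM} the mean
#' over glial leaf types; optional multiplicative log-normal noise is applied,
#' and the result is log2(x+1)-transformed. Contamination is mixed in linear
#' space because contaminating RNA is additive material, not additive log
#' signal. The profile is deliberately not re-normalized to CPM: a
#' low-quality extraction detects less mRNA overall, which is exactly the
#' signal the normalized marker sum measures.
#'
#' @param tax A [ReferenceTaxonomy-class].
#' @param specs data.frame from [cellSimSpec()].
#' @param seed integer.
#' @param noiseSd log2-space noise SD (0 = deterministic profiles).
#' @return list with \code{exprs} (genes x cells, log2(CPM+1)) and
#'   \code{truth} (the specs plus cell ids).
#' @examples
#' tax <- makeReference(synthConfig(seed = 1, nGenes = 500))
#' cells <- makePatchseqCells(tax, cellSimSpec(leafTypes(tax)[1]), seed = 2)
#' @export
makePatchseqCells <- function(tax, specs, seed = 1L, noiseSd = 0.2) {
  unknown <- setdiff(specs$trueType, leafTypes(tax))
  if (length(unknown)) {
    stop("unknown leaf type id(s): ", paste(unique(unknown), collapse = ", "))
  }
  typeCPM <- 2^tax@typeMeans - 1
  gliaLeaves <- leafTypes(tax)[tax@classOf[leafTypes(tax)] %in%
                                 names(tax@isGlia)[tax@isGlia]]
  gliaCPM <- if (length(gliaLeaves)) {
    rowMeans(typeCPM[, gliaLeaves, drop = FALSE])
  } else {
    rep(0, nrow(typeCPM))
  }
  if (!length(gliaLeaves) && any(specs$contaminationFraction > 0)) {
    stop("taxonomy has no glial classes to contaminate with")
  }
  n <- nrow(specs)
  withSeed(seed, {
    exprs <- matrix(0, nrow = nrow(tax@exprs), ncol = n,
                    dimnames = list(rownames(tax@exprs),
                                    sprintf("ps%04d", seq_len(n))))
    for (j in seq_len(n)) {
      lin <- specs$qualityFactor[j] * typeCPM[, specs$trueType[j]] +
        specs$contaminationFraction[j] * gliaCPM
      if (noiseSd > 0) lin <- lin * 2^stats::rnorm(length(lin), 0, noiseSd)
      exprs[, j] <- log2(lin + 1)
    }
    truth <- cbind(data.frame(cellId = colnames(exprs),
                              stringsAsFactors = FALSE), specs)
    list(exprs = exprs, truth = truth)
  })
}
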