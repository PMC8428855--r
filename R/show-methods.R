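#' @describeIn ReferenceTaxonomy-class compact display.
#' @param object object to display.
#' @export
setMethod("show", "ReferenceTaxonomy", function(object) {
  leaves <- leafTypes(object)
  cat("ReferenceTaxonomy:", length(names(object@isGlia)), "classes,",
      length(leaves), "leaf types,", ncol(object@exprs), "reference cells,",
      nrow(object@exprs), "genes\n")
  cat("  classes:", paste(names(object@isGlia), collapse = ", "), "\n")
  cat("  glial:", paste(names(object@isGlia)[object@isGlia],
                        collapse = ", "), "\n")
})

#' @describeIn VoltageSweep-class compact display.
#' @export
setMethod("show", "VoltageSweep", function(object) {
  cat(sprintf("VoltageSweep: %.3f s at %.1f kHz (%d samples), %d epoch(s)\n",
              sweepDuration(object), 1 / object@dt / 1000,
              length(object@voltage), nrow(object@epochs)))
  if (nrow(object@epochs)) {
    print(object@epochs, row.names = FALSE)
  }
})

#' @describeIn QCVerdict-class compact display.
#' @export
setMethod("show", "QCVerdict", function(object) {
  cat("QCVerdict:", if (object@passed) "PASS" else
    paste("FAIL [", paste(object@reasons, collapse = ", "), "]"), "\n")
  if (length(object@measured)) {
    cat(paste(sprintf("  %s = %.4g", names(object@measured),
                      object@measured), collapse = "\n"), "\n")
  }
})

#' @describeIn MappingResult-class compact display.
#' @export
setMethod("show", "MappingResult", function(object) {
  cat(sprintf("MappingResult: %s (p = %.2f, n_boot = %d)\n",
              object@assignedType, max(object@probabilities), object@nBoot))
  if (!is.na(object@consistency)) {
    cat(sprintf("  kl = %.3f, correlation = %.3f, consistency = %s\n",
                object@kl, object@typeCorrelation, object@consistency))
  }
})

#' @describeIn FeatureMatrix-class compact display.
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "cells x",
      ncol(object@values), "features\n")
  if (length(object@category)) {
    tab <- table(object@category)
    cat("  per category:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  if (length(object@dropped)) {
    cat("  dropped cells:", paste(object@dropped, collapse = ", "), "\n")
  }
})

#' @describeIn SparsePCResult-class compact display.
#' @export
setMethod("show", "SparsePCResult", function(object) {
  kept <- sum(vapply(object@kept, sum, 1L))
  cat("SparsePCResult:", kept, "components kept (adjusted EV >",
      object@retention, ") across", length(object@kept), "categories\n")
})

#' @describeIn ROCResult-class compact display.
#' @export
setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC = %.4f (%d thresholds, direction = %s)\n",
              object@auc, length(object@thresholds), object@direction))
})

#' @describeIn FeatureMatrix-class feature values matrix accessor.
#' @param fm A \code{FeatureMatrix}.
#' @export
featureValues <- function(fm) fm@values

#' @describeIn FeatureMatrix-class per-column category labels.
#' @export
featureCategories <- function(fm) fm@category

#' @describeIn SparsePCResult-class combined z-scored score matrix.
#' @param res A \code{SparsePCResult}.
#' @export
spcaScores <- function(res) res@scores

#' @describeIn SparsePCResult-class adjusted explained variance per category.
#' @export
spcaAdjEV <- function(res) res@adjEV

#' @describeIn MappingResult-class bootstrap probability vector.
#' @param result A \code{MappingResult}.
#' @export
mappingProbabilities <- function(result) result@probabilities

#' @describeIn MappingResult-class consistency label.
#' @export
mappingConsistency <- function(result) result@consistency

#' @describeIn QCVerdict-class pass flag.
#' @param verdict A \code{QCVerdict}.
#' @export
qcPassed <- function(verdict) verdict@passed

#' @describeIn QCVerdict-class coded failure reasons.
#' @export
qcReasons <- function(verdict) verdict@reasons

#' @describeIn QCVerdict-class measured metric values.
#' @export
qcMeasured <- function(verdict) verdict@measured
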